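random_profiles <- function(G, d, seed = 1) {
  set.seed(seed)
  matrix(rnorm(G * d), G, dimnames = list(sprintf("G%05d", seq_len(G)),
                                          sprintf("t%d", seq_len(d))))
}

test_that("SOM training is deterministic and order-insensitive", {
  X <- random_profiles(150, 6, seed = 61)
  cfg <- analysis_config(som_rows = 5, som_cols = 5, som_epochs = 15)
  m1 <- train_som(X, cfg, seed = 9)
  m2 <- train_som(X, cfg, seed = 9)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$mapping, m2$mapping)

  # caller row order is irrelevant (canonical sort before the seeded shuffle)
  m3 <- train_som(X[sample(nrow(X)), ], cfg, seed = 9)
  expect_identical(m1$codebook, m3$codebook)
  expect_identical(m1$mapping, m3$mapping)

  m4 <- train_som(X, cfg, seed = 10)
  expect_false(identical(m1$mapping, m4$mapping))
})

test_that("training does not increase the quantization error", {
  X <- random_profiles(400, 8, seed = 62)
  cfg <- analysis_config(som_rows = 6, som_cols = 6, som_epochs = 20)
  m <- train_som(X, cfg, seed = 1)
  expect_lte(m$qe_final, m$qe_initial)
  expect_equal(sum(m$unit_counts), nrow(X))
  expect_true(all(m$unit_quality >= 0, na.rm = TRUE))
})

test_that("a single-unit map converges to the data mean", {
  # rows share one profile up to scale and offset, so standardization
  # collapses them onto a single vector: the lone codebook must reach it
  set.seed(63)
  base <- rnorm(5)
  X <- outer(runif(80, 0.5, 2), base) + rnorm(80)
  rownames(X) <- sprintf("G%05d", 1:80)
  colnames(X) <- sprintf("t%d", 1:5)
  cfg <- analysis_config(som_rows = 1, som_cols = 1, som_epochs = 200)
  m <- train_som(X, cfg, seed = 2)
  target <- colMeans(t(scale(t(X))))
  expect_lt(max(abs(m$codebook[1, ] - target)), 1e-3)
  # constant-profile genes are dropped with a record
  X2 <- rbind(X, CONST = rep(1, 5))
  m2 <- train_som(X2, cfg, seed = 2)
  expect_identical(m2$dropped, "CONST")
})

test_that("unit occupancy is near-uniform on isotropic data", {
  X <- random_profiles(4000, 8, seed = 64)
  cfg <- analysis_config(som_rows = 20, som_cols = 20, som_epochs = 8)
  m <- train_som(X, cfg, seed = 3)
  expect_equal(mean(m$unit_counts), nrow(X) / 400)
  expect_lt(max(m$unit_counts) / mean(m$unit_counts), 5)
})

test_that("the gap statistic matches an independent recomputation", {
  set.seed(65)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(12 * 2, sd = 0.5), 12), 2, centers[i, ], "+")))
  ref_sets <- lapply(1:12, function(b) {
    rng <- apply(x, 2, range)
    m <- matrix(runif(nrow(x) * 2), nrow(x))
    sweep(sweep(m, 2, rng[2, ] - rng[1, ], "*"), 2, rng[1, ], "+")
  })
  out <- gap_statistic_k(x, k_max = 4, ref_sets = ref_sets)

  # oracle: recompute W, gap and the selection rule from scratch
  ks <- 1:5
  logW <- sapply(ks, function(k) {
    cl <- if (k == 1) rep(1, nrow(x)) else
      cluster::pam(x, k, cluster.only = TRUE)
    log(wk_oracle(x, cl))
  })
  logWstar <- sapply(ref_sets, function(r)
    sapply(ks, function(k) {
      cl <- if (k == 1) rep(1, nrow(r)) else
        cluster::pam(r, k, cluster.only = TRUE)
      log(wk_oracle(r, cl))
    }))
  gap <- rowMeans(logWstar) - logW
  se <- apply(logWstar, 1, sd) * sqrt(1 + 1 / length(ref_sets))
  chosen <- 4
  for (k in 1:4) if (gap[k] >= gap[k + 1] - se[k + 1]) { chosen <- k; break }

  expect_equal(out$table$logW, logW)
  expect_equal(out$table$gap, gap)
  expect_equal(out$table$se, se)
  expect_equal(out$k, chosen)
  expect_equal(out$k, 3)  # three well-separated blobs
})

test_that("gap statistic edge cases: k_max one and a single blob", {
  set.seed(66)
  x <- matrix(rnorm(40 * 3), 40)
  expect_equal(gap_statistic_k(x, k_max = 1, B = 12, seed = 1)$k, 1)
  expect_equal(gap_statistic_k(x, k_max = 5, B = 20, seed = 1)$k, 1)
  # zero-range dimensions are dropped with a warning
  x2 <- cbind(x, 7)
  expect_warning(out <- gap_statistic_k(x2, k_max = 3, B = 12, seed = 1),
                 "zero-range")
  expect_equal(out$k, 1)
})

test_that("planted clusters are recovered across seeds", {
  found <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    centers <- matrix(rnorm(4 * 5, sd = 10), 4)
    x <- do.call(rbind, lapply(1:4, function(i)
      sweep(matrix(rnorm(15 * 5), 15), 2, centers[i, ], "+")))
    out <- gap_statistic_k(x, k_max = 6, B = 15, seed = seed)
    if (out$k == 4) found <- found + 1L
  }
  expect_gte(found, 18)
})

test_that("cluster summaries exclude sentinel entries and report gaps", {
  X <- random_profiles(60, 4, seed = 67)
  cfg <- analysis_config(som_rows = 3, som_cols = 3, som_epochs = 10,
                         kmedoid_k_max = 3, gap_B = 10)
  m <- train_som(X, cfg, seed = 5)
  m <- assign_unit_clusters(m, cfg, k = 2)
  lcpm <- lcpm_long(matrix(c(4, 6), 60, 2, byrow = TRUE,
                           dimnames = list(rownames(X), c("tA", "tB"))))
  cs <- cluster_summaries(m, lcpm, cfg)
  expect_equal(cs$mean_lcpm[cs$tissue == "tA"], rep(4, 2))
  expect_equal(cs$mean_lcpm[cs$tissue == "tB"], rep(6, 2))

  # a tissue where one cluster's genes are all sentinel is missing, not 0
  g1 <- names(m$mapping)[m$unit_cluster[m$mapping] == 1]
  lcpm$lcpm[lcpm$gene_id %in% g1 & lcpm$tissue == "tA"] <- -21
  cs2 <- cluster_summaries(m, lcpm, cfg)
  expect_true(is.na(cs2$mean_lcpm[cs2$cluster_id == 1 & cs2$tissue == "tA"]))
  expect_equal(cs2$mean_lcpm[cs2$cluster_id == 2 & cs2$tissue == "tA"], 4)
})

test_that("map input rule keeps genes DE somewhere but not everywhere", {
  mk <- function(dirs) data.frame(gene_id = sprintf("G%d", seq_along(dirs)),
                                  analysis_id = "x", log2fc = 1,
                                  pvalue = 0.5, fdr = 0.5,
                                  direction = dirs,
                                  stringsAsFactors = FALSE)
  de <- list(a = mk(c("up", "up", "ns", "ns")),
             b = mk(c("up", "ns", "ns", "down")))
  expect_identical(som_input_genes(de), c("G2", "G4"))
})
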