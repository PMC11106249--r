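make_filter_toy <- function(genes, tissue) {
  # pads every column to library size 1e6 with a filler gene
  counts <- do.call(rbind, genes)
  filler <- 1e6 - colSums(counts)
  counts <- rbind(counts, FILLER = filler)
  rownames(counts) <- toupper(rownames(counts))
  colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  cm <- count_matrix(counts)
  meta <- make_meta(colnames(counts), tissue = tissue, role = "control")
  list(cm = cm, meta = meta)
}

test_that("expression filter applies the per-tissue and total CPM rules", {
  toy <- make_filter_toy(list(zero = c(0, 0, 0, 0),
                              within1 = c(12, 12, 0, 0),
                              nowhere = c(12, 2, 12, 2),
                              boundary = c(10, 10, 0, 0)),
                         tissue = rep(c("skin", "bone"), each = 2))
  kept <- filter_by_expression(toy$cm, toy$meta, analysis_config())$gene_ids
  expect_false("ZERO" %in% kept)
  expect_true("WITHIN1" %in% kept)     # all of tissue 1 >= 10, total 24 >= 15
  expect_false("NOWHERE" %in% kept)    # no tissue has every sample >= 10
  expect_true("BOUNDARY" %in% kept)    # inclusive boundaries: 10 and 20

  # 1-tissue boundary case: CPM (10, 10), total 20
  toy2 <- make_filter_toy(list(g = c(10, 10)), tissue = c("skin", "skin"))
  expect_true("G" %in%
                filter_by_expression(toy2$cm, toy2$meta)$gene_ids)
  # total-CPM rule can reject on its own
  cfg2 <- analysis_config(cpm_total_min = 25)
  expect_false("G" %in%
                 filter_by_expression(toy2$cm, toy2$meta, cfg2)$gene_ids)
})

test_that("raising cpm_min never enlarges the kept-gene set", {
  set.seed(1)
  counts <- matrix(rnbinom(200 * 6, mu = 40, size = 5), 200,
                   dimnames = list(sprintf("G%03d", 1:200),
                                   sprintf("s%d", 1:6)))
  cm <- count_matrix(counts)
  meta <- make_meta(colnames(counts),
                    tissue = rep(c("skin", "bone", "muscle"), each = 2),
                    role = rep(c("control", "control", "somatic"), each = 2))
  prev <- cm$gene_ids
  for (thr in c(1, 5, 10, 50, 200)) {
    kept <- filter_by_expression(cm, meta,
                                 analysis_config(cpm_min = thr))$gene_ids
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("TMM factors match the hand-coded trimmed-mean oracle", {
  counts <- matrix(c(100, 200, 300, 400, 500, 600,
                     110, 190, 310, 390, 510, 590,
                     100, 200, 300, 400, 500, 60000), 6,
                   dimnames = list(sprintf("G%d", 1:6), c("a", "b", "c")))
  cm <- count_matrix(counts)
  nf <- tmm_factors(cm)
  expect_equal(nf$tmm_factor, unname(tmm_oracle(counts)), tolerance = 1e-6)
  expect_equal(exp(mean(log(nf$tmm_factor))), 1, tolerance = 1e-9)
  expect_equal(nf$effective_libsize,
               unname(colSums(counts)) * nf$tmm_factor)
})

test_that("TMM factors obey scale and composition invariances", {
  set.seed(7)
  counts <- matrix(rnbinom(300 * 4, mu = 100, size = 5), 300,
                   dimnames = list(sprintf("G%03d", 1:300),
                                   sprintf("s%d", 1:4)))
  cm <- count_matrix(counts)
  nf <- tmm_factors(cm)
  expect_equal(exp(mean(log(nf$tmm_factor))), 1, tolerance = 1e-9)

  # identical columns: all factors one
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- c("x", "y", "z")
  expect_equal(tmm_factors(count_matrix(same))$tmm_factor, rep(1, 3))

  # doubling an entire column is absorbed by the library size
  doubled <- cbind(counts[, 1, drop = FALSE] * 2, counts[, 1, drop = FALSE])
  colnames(doubled) <- c("x2", "x")
  expect_equal(tmm_factors(count_matrix(doubled))$tmm_factor, rep(1, 2),
               tolerance = 1e-12)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3
  nf2 <- tmm_factors(count_matrix(scaled))
  # invariant up to the precision weights, which see absolute counts
  expect_equal(nf2$tmm_factor, nf$tmm_factor, tolerance = 5e-3)
})

test_that("grouped LCPM applies the formula, sentinel and retention rule", {
  counts <- rbind(A = c(400, 300, 300, 5, 5, 5),
                  B = c(0, 0, 0, 50, 50, 50),
                  C = c(12, 11, 4, 0, 0, 0),   # >= 10 in 2/3 of tissue 1
                  D = c(9, 8, 7, 6, 5, 4))     # never 10 in 2/3 anywhere
  filler <- matrix(rep((1e6 / 3) - colSums(counts) / 3, each = 3), 3,
                   byrow = FALSE)
  filler <- round(filler)
  rownames(filler) <- c("F1", "F2", "F3")
  counts <- rbind(counts, filler)
  colnames(counts) <- sprintf("s%d", 1:6)
  cm <- count_matrix(counts)
  meta <- make_meta(colnames(counts),
                    tissue = rep(c("skin", "bone"), each = 3),
                    role = "control")
  nf <- unit_factors(cm)
  cfg <- analysis_config()
  lc <- grouped_lcpm(cm, meta, nf, cfg)

  a_skin <- lc$lcpm[lc$gene_id == "A" & lc$tissue == "skin"]
  expect_equal(a_skin,
               log2((1000 + 0.5) / sum(cm$library_sizes[1:3]) * 1e6))
  b_skin <- lc$lcpm[lc$gene_id == "B" & lc$tissue == "skin"]
  expect_identical(b_skin, -21)          # sentinel iff zero group count
  expect_true(all((lc$lcpm == -21) == (lc$gene_id == "B" &
                                         lc$tissue == "skin" |
                                         lc$gene_id == "C" &
                                         lc$tissue == "bone")))
  expect_true("C" %in% lc$gene_id)       # two-thirds boundary is inclusive
  expect_false("D" %in% lc$gene_id)
})

test_that("grouped LCPM agrees with direct evaluation on random data", {
  set.seed(3)
  counts <- matrix(rnbinom(50 * 6, mu = 500, size = 5), 50,
                   dimnames = list(sprintf("G%02d", 1:50),
                                   sprintf("s%d", 1:6)))
  cm <- count_matrix(counts)
  meta <- make_meta(colnames(counts),
                    tissue = rep(c("skin", "bone"), each = 3),
                    role = "control")
  nf <- tmm_factors(cm)
  lc <- grouped_lcpm(cm, meta, nf, analysis_config())
  eff <- nf$effective_libsize
  for (g in c("G01", "G33")) {
    expect_equal(lc$lcpm[lc$gene_id == g & lc$tissue == "skin"],
                 log2((sum(counts[g, 1:3]) + 0.5) / sum(eff[1:3]) * 1e6))
    expect_equal(lc$lcpm[lc$gene_id == g & lc$tissue == "bone"],
                 log2((sum(counts[g, 4:6]) + 0.5) / sum(eff[4:6]) * 1e6))
  }
})
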