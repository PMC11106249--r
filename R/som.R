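#' Train a self-organizing map on gene expression profiles
#'
#' Online Kohonen training on a rectangular grid with a Gaussian
#' neighborhood and sum-of-squares distances. Each gene's profile is
#' standardized to mean zero and unit standard deviation across tissues
#' (constant profiles are dropped and recorded). The learning rate declines
#' linearly from `som_alpha_start` to `som_alpha_end`; the neighborhood
#' radius declines linearly from two-thirds of the grid diagonal (rounded
#' up) to one over the first two-thirds of training and holds there, so the
#' final third updates only each observation's best-matching unit
#' (k-means-like fine tuning). Rows are first
#' sorted by gene id and then shuffled under the run seed, so the result is
#' independent of the caller's row order and bit-reproducible for a given
#' seed.
#'
#' @param profiles Numeric gene-by-tissue matrix with gene row names
#'   (typically log-CPM columns concatenated across taxa).
#' @param cfg An [analysis_config()] (grid size, epochs, learning rates).
#' @param seed Integer seed for initialization and presentation order.
#' @return An object of class `som_model`: `grid` (rows, cols), `codebook`
#'   (units by tissues), `mapping` (named unit index per gene),
#'   `unit_counts`, `unit_quality` (mean sum-of-squares distance of mapped
#'   genes to their unit), `unit_neighbor_dist` (mean sum-of-squares
#'   distance to grid neighbors), `qe_initial`/`qe_final` (quantization
#'   error before and after training), `dropped` (constant-profile genes),
#'   and `unit_cluster`/`k` once [assign_unit_clusters()] has run.
#' @export
train_som <- function(profiles, cfg = analysis_config(), seed = cfg$rng_seed) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  if (anyNA(profiles)) stop("profiles must not contain missing values")
  sds <- apply(profiles, 1, stats::sd)
  dropped <- rownames(profiles)[sds == 0]
  profiles <- profiles[sds > 0, , drop = FALSE]
  X <- t(scale(t(profiles)))  # per-gene standardization
  G <- nrow(X)
  U <- cfg$som_rows * cfg$som_cols
  if (G < U)
    warning(sprintf("fewer genes (%d) than map units (%d)", G, U))

  # canonical order, then a seeded shuffle: caller row order is irrelevant
  X <- X[order(rownames(X)), , drop = FALSE]
  set.seed(seed)
  X <- X[sample(G), , drop = FALSE]

  grid <- as.matrix(expand.grid(row = seq_len(cfg$som_rows),
                                col = seq_len(cfg$som_cols)))
  init_idx <- sample(G, U, replace = G < U)
  codebook0 <- X[init_idx, , drop = FALSE]
  rownames(codebook0) <- NULL
  ord <- as.vector(vapply(seq_len(cfg$som_epochs),
                          function(e) sample.int(G), integer(G)))
  r0 <- max(1, ceiling(2 / 3 * sqrt((cfg$som_rows - 1)^2 +
                                      (cfg$som_cols - 1)^2)))
  fit <- som_train_cpp(X, codebook0, grid, ord,
                       cfg$som_alpha_start, cfg$som_alpha_end, r0, 1)
  mapping <- stats::setNames(fit$mapping, rownames(X))
  mapping <- mapping[order(names(mapping))]
  bmu_dist <- stats::setNames(fit$bmu_dist, rownames(X))[names(mapping)]

  unit_counts <- tabulate(mapping, nbins = U)
  unit_quality <- rep(NA_real_, U)
  agg <- tapply(bmu_dist, mapping, mean)
  unit_quality[as.integer(names(agg))] <- agg
  cb <- fit$codebook
  nb <- vapply(seq_len(U), function(u) {
    d2 <- (grid[, 1] - grid[u, 1])^2 + (grid[, 2] - grid[u, 2])^2
    nbr <- which(d2 > 0 & d2 <= 2)  # the 8 surrounding grid cells
    if (!length(nbr)) return(NA_real_)
    mean(rowSums((cb[nbr, , drop = FALSE] -
                    matrix(cb[u, ], length(nbr), ncol(cb),
                           byrow = TRUE))^2))
  }, numeric(1))

  structure(list(grid = c(rows = cfg$som_rows, cols = cfg$som_cols),
                 grid_coords = grid,
                 codebook = cb, mapping = mapping,
                 unit_counts = unit_counts, unit_quality = unit_quality,
                 unit_neighbor_dist = nb,
                 qe_initial = som_qe_cpp(X, codebook0),
                 qe_final = som_qe_cpp(X, fit$codebook),
                 dropped = dropped, unit_cluster = NULL, k = NULL,
                 seed = seed),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d grid, %d genes mapped, QE %.4f -> %.4f\n",
              x$grid["rows"], x$grid["cols"], length(x$mapping),
              x$qe_initial, x$qe_final))
  if (!is.null(x$k)) cat(sprintf("  %d k-medoid unit clusters\n", x$k))
  invisible(x)
}

# Tibshirani-style within-cluster dispersion: sum over clusters of the
# within-cluster sum of pairwise squared Euclidean distances over 2 n_r.
within_dispersion <- function(d2, clusters) {
  sum(vapply(split(seq_along(clusters), clusters), function(idx)
    sum(d2[idx, idx]) / (2 * length(idx)), numeric(1)))
}

pam_clusters <- function(x, k) {
  if (k == 1) rep(1L, nrow(x)) else
    cluster::pam(x, k, cluster.only = TRUE)
}

#' Choose the number of k-medoid clusters by the gap statistic
#'
#' Runs k-medoids (PAM) on the codebook vectors for `k = 1..k_max` and
#' compares `log W_k` (within-cluster dispersion: half the mean pairwise
#' squared Euclidean distance summed within clusters) with its expectation
#' under `B` reference datasets drawn uniformly over the observed
#' per-dimension ranges. The chosen `k` is the smallest with
#' `Gap(k) >= Gap(k+1) - s_{k+1}`, where
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`.
#'
#' @param codebook Numeric matrix of unit vectors (or any observations).
#' @param k_max Largest k considered (must be below the number of rows).
#' @param B Number of reference datasets (>= 10).
#' @param seed Integer seed for the reference draws.
#' @param ref_sets Optional list of pre-drawn reference matrices (used by
#'   verification code); overrides `B` and `seed`.
#' @return A list with `k` (chosen count), `table` (per-k `logW`, `gap`,
#'   `se`) and `clusters` (PAM assignment at the chosen k).
#' @export
gap_statistic_k <- function(codebook, k_max, B = 50, seed = 1L,
                            ref_sets = NULL) {
  stopifnot(is.matrix(codebook), k_max >= 1)
  if (k_max >= nrow(codebook)) stop("k_max must be below the number of units")
  if (is.null(ref_sets) && B < 10) stop("B must be at least 10")
  rng <- apply(codebook, 2, range)
  span <- rng[2, ] - rng[1, ]
  keep_dim <- span > 0
  if (!all(keep_dim)) {
    warning("dropping zero-range dimensions: ",
            paste(which(!keep_dim), collapse = ", "))
    codebook <- codebook[, keep_dim, drop = FALSE]
    rng <- rng[, keep_dim, drop = FALSE]
  }
  n <- nrow(codebook)
  ks <- seq_len(min(k_max + 1L, n - 1L))  # need Gap(k+1) for the rule
  d2 <- as.matrix(stats::dist(codebook))^2
  logW <- vapply(ks, function(k)
    log(within_dispersion(d2, pam_clusters(codebook, k))), numeric(1))

  if (is.null(ref_sets)) {
    set.seed(seed)
    ref_sets <- lapply(seq_len(B), function(b) {
      m <- matrix(stats::runif(n * ncol(codebook)), n)
      sweep(sweep(m, 2, rng[2, ] - rng[1, ], "*"), 2, rng[1, ], "+")
    })
  }
  B <- length(ref_sets)
  logWstar <- vapply(ref_sets, function(ref) {
    rd2 <- as.matrix(stats::dist(ref))^2
    vapply(ks, function(k)
      log(within_dispersion(rd2, pam_clusters(ref, k))), numeric(1))
  }, numeric(length(ks)))
  logWstar <- matrix(logWstar, nrow = length(ks))
  gap <- rowMeans(logWstar) - logW
  se <- apply(logWstar, 1, stats::sd) * sqrt(1 + 1 / B)

  chosen <- min(k_max, length(ks))
  for (k in seq_len(min(k_max, length(ks) - 1L))) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) { chosen <- k; break }
  }
  list(k = chosen,
       table = data.frame(k = ks, logW = logW, gap = gap, se = se),
       clusters = pam_clusters(codebook, chosen))
}

#' Cluster the SOM units by k-medoids with gap-statistic selection
#'
#' @param model A [train_som()] model.
#' @param cfg An [analysis_config()] (`kmedoid_k_max`, `gap_B`).
#' @param seed Seed for the gap-statistic reference draws.
#' @param k Optional fixed cluster count bypassing the gap statistic.
#' @return The model with `unit_cluster`, `k` and `gap_table` filled in.
#' @export
assign_unit_clusters <- function(model, cfg = analysis_config(),
                                 seed = model$seed, k = NULL) {
  stopifnot(inherits(model, "som_model"))
  if (is.null(k)) {
    gs <- gap_statistic_k(model$codebook, cfg$kmedoid_k_max, cfg$gap_B, seed)
    model$k <- gs$k
    model$unit_cluster <- as.integer(gs$clusters)
    model$gap_table <- gs$table
  } else {
    model$k <- as.integer(k)
    model$unit_cluster <- as.integer(pam_clusters(model$codebook, k))
  }
  model
}

#' Genes eligible for the expression map
#'
#' The map is built from genes significantly differentially expressed in at
#' least one test-tissue analysis but not in every one of them.
#'
#' @param de_tables Named list of DE tables from [fit_de()] (all test-tissue
#'   analyses across taxa).
#' @return Character vector of gene ids.
#' @export
som_input_genes <- function(de_tables) {
  genes <- sort(unique(unlist(lapply(de_tables, `[[`, "gene_id"))))
  sig <- vapply(de_tables, function(de) {
    v <- de$direction[match(genes, de$gene_id)]
    !is.na(v) & v != "ns"
  }, logical(length(genes)))
  sig <- matrix(sig, nrow = length(genes))
  n_sig <- rowSums(sig)
  genes[n_sig >= 1 & n_sig < length(de_tables)]
}

#' Merge per-taxon grouped LCPM tables into one profile matrix
#'
#' Takes the intersection of gene symbols across taxa and concatenates the
#' tissue columns, labelled `taxon.tissue`.
#'
#' @param lcpm_tables Named list (by taxon) of [grouped_lcpm()] tables.
#' @param genes Optional gene subset (e.g. from [som_input_genes()]).
#' @return Numeric gene-by-profile matrix.
#' @export
merge_lcpm_profiles <- function(lcpm_tables, genes = NULL) {
  mats <- lapply(names(lcpm_tables), function(tx) {
    m <- lcpm_matrix(lcpm_tables[[tx]])
    colnames(m) <- paste(tx, colnames(m), sep = ".")
    m
  })
  common <- Reduce(intersect, lapply(mats, rownames))
  if (!is.null(genes)) common <- intersect(common, genes)
  common <- sort(common)
  do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
}

#' Per-cluster, per-tissue mean expression
#'
#' Means of the (unclipped) log-CPM of the genes mapped to each cluster's
#' units, excluding sentinel entries (zero-count groups); a (cluster,
#' tissue) pair with no valid entries is reported as missing, not zero.
#'
#' @param model A clustered [train_som()] model (after
#'   [assign_unit_clusters()]).
#' @param lcpm A long grouped-LCPM table covering the mapped genes; its
#'   `tissue` column may be the merged `taxon.tissue` labels.
#' @param cfg An [analysis_config()] (for the sentinel value).
#' @return A data frame `cluster_id`, `tissue`, `mean_lcpm`, `n_genes`.
#' @export
cluster_summaries <- function(model, lcpm, cfg = analysis_config()) {
  stopifnot(inherits(model, "som_model"))
  if (is.null(model$unit_cluster))
    stop("model has no unit clusters; run assign_unit_clusters() first")
  gene_cluster <- model$unit_cluster[model$mapping]
  names(gene_cluster) <- names(model$mapping)
  lcpm <- lcpm[lcpm$gene_id %in% names(gene_cluster), , drop = FALSE]
  cl <- gene_cluster[lcpm$gene_id]
  valid <- lcpm$lcpm != cfg$lcpm_zero_sentinel
  out <- expand.grid(cluster_id = sort(unique(model$unit_cluster)),
                     tissue = sort(unique(lcpm$tissue)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_lcpm <- NA_real_
  out$n_genes <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- cl == out$cluster_id[i] & lcpm$tissue == out$tissue[i] & valid
    if (any(sel)) {
      out$mean_lcpm[i] <- mean(lcpm$lcpm[sel])
      out$n_genes[i] <- sum(sel)
    }
  }
  out[order(out$cluster_id, out$tissue), , drop = FALSE]
}
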