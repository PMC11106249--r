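# Independent oracles and small data builders shared across tests.

# Build a valid metadata table for toy datasets.
make_meta <- function(sample_id, tissue, role, taxon = "cattle",
                      age = NULL, sex = NULL, species = "bos_taurus") {
  n <- length(sample_id)
  data.frame(sample_id = sample_id, taxon = taxon, tissue = tissue,
             role = role,
             age = if (is.null(age)) rep("adult", n) else age,
             sex = if (is.null(sex)) rep(c("female", "male"),
                                         length.out = n) else sex,
             species = species,
             replicate = stats::ave(seq_len(n), tissue,
                                    FUN = seq_along),
             stringsAsFactors = FALSE)
}

# Hand-coded TMM from the published definition: doubly trimmed (30% on M,
# 5% on A), precision-weighted mean of log ratios against the reference
# sample whose 75th-percentile count/library-size is closest to the mean,
# rescaled to geometric mean one.
tmm_oracle <- function(counts, lib = colSums(counts)) {
  q75 <- apply(counts, 2, stats::quantile, p = 0.75) / lib
  ref <- which.min(abs(q75 - mean(q75)))
  one_factor <- function(j) {
    obs <- counts[, j]; nO <- lib[j]
    rf <- counts[, ref]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f / exp(mean(log(f)))
}

# Brute-force BH step-up: sort, take cumulative minima of p * m / rank from
# the largest rank down, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

# Explicit hypergeometric upper tail from binomial coefficients.
hyper_tail_oracle <- function(k, N, K, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Direct rule application for one gene's homology status: same direction in
# >= 1 analysis of each ingroup, and no same-direction outgroup signal.
homology_oracle <- function(a, b, outg) {
  sig <- function(v) v[v %in% c("up", "down")]
  shared <- intersect(unique(sig(a)), unique(sig(b)))
  if (!length(sig(a)) && !length(sig(b))) return(NA_character_)
  if (!length(shared)) return("not_shared")
  dir <- if (length(shared) > 1) {
    support <- vapply(shared, function(d) sum(a == d) + sum(b == d),
                      numeric(1))
    shared[order(-support, match(shared, c("up", "down")))][1]
  } else shared
  if (any(outg == dir)) "excluded_outgroup" else "homologous"
}

# Tibshirani-style within dispersion for the gap-statistic oracle.
wk_oracle <- function(x, clusters) {
  d2 <- as.matrix(stats::dist(x))^2
  sum(vapply(split(seq_along(clusters), clusters), function(idx)
    sum(d2[idx, idx]) / (2 * length(idx)), numeric(1)))
}

# NB toy counts for DE tests: two groups (test tissue vs somatic organs).
# A planted log2 fold change applies to the first n_de genes only, so it is
# a genuine differential signal rather than a library-size shift.
nb_two_group <- function(G, n_per = 3, mu = 100, phi = 0.1, lfc = 0,
                         n_de = if (lfc == 0) 0 else G, seed = 1) {
  set.seed(seed)
  mu_test <- rep(mu, G)
  if (n_de > 0) mu_test[seq_len(n_de)] <- mu * 2^lfc
  test <- matrix(rnbinom(G * n_per, mu = mu_test, size = 1 / phi), G)
  ctl <- matrix(rnbinom(G * n_per, mu = mu, size = 1 / phi), G)
  counts <- cbind(test, ctl)
  rownames(counts) <- sprintf("G%05d", seq_len(G))
  colnames(counts) <- c(sprintf("t%d", seq_len(n_per)),
                        sprintf("c%d", seq_len(n_per)))
  meta <- make_meta(colnames(counts),
                    tissue = c(rep("skin", n_per),
                               rep(c("muscle", "kidney", "heart", "liver",
                                     "spleen", "lung"),
                                   length.out = n_per)),
                    role = c(rep("control", n_per), rep("somatic", n_per)))
  list(cm = count_matrix(counts), meta = meta)
}

# Minimal DE table with prescribed directions.
de_tab_acc <- function(genes, dirs, analysis = "x") {
  lfc <- ifelse(dirs == "up", 2, ifelse(dirs == "down", -2, 0))
  fdr <- ifelse(dirs == "ns", 0.9, 0.01)
  data.frame(gene_id = genes, analysis_id = analysis, log2fc = lfc,
             pvalue = fdr / 2, fdr = fdr, direction = dirs,
             stringsAsFactors = FALSE)
}

# Uniform normalization factors for toy fits that skip TMM.
unit_factors <- function(cm) {
  data.frame(sample_id = cm$sample_ids, tmm_factor = 1,
             effective_libsize = unname(cm$library_sizes),
             stringsAsFactors = FALSE)
}

# A long grouped-LCPM table from a named matrix (genes x tissues).
lcpm_long <- function(m, taxon = "ingroup_a") {
  data.frame(gene_id = rep(rownames(m), ncol(m)),
             taxon = taxon,
             tissue = rep(colnames(m), each = nrow(m)),
             lcpm = as.vector(m), stringsAsFactors = FALSE)
}
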