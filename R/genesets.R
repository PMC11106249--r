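#' Competitive gene-set ranking with inter-gene correlation
#'
#' For each gene set, compares the mean standardized statistic of member
#' genes with that of non-members using a two-sample location test whose
#' set-mean variance is inflated by the variance inflation factor
#' `VIF = 1 + (m - 1) * rho`, where `rho` is the mean pairwise correlation
#' of the member genes' residual expression profiles (floored at zero, so
#' VIF >= 1 and the test never becomes anti-conservative). With `rho = 0`
#' this reduces to a standard equal-variance two-sample t-test. P-values are
#' two-sided and BH-adjusted across sets; the reported direction is
#' overexpressed (`Up`) or underexpressed (`Down`) by the sign of the set
#' mean.
#'
#' @param gene_stats Named numeric vector of per-gene standardized
#'   statistics for one analysis (see [de_zscores()]).
#' @param sets A gene-set collection from [read_gmt()] (or a list with
#'   `name` and `members` entries).
#' @param residuals Gene-by-sample residual matrix on the log-CPM scale
#'   (see [lcpm_residuals()]); rows must be named by gene id. Ignored when
#'   `fixed_rho` is given.
#' @param analysis_id Label copied into the output.
#' @param fixed_rho Optional fixed inter-gene correlation overriding the
#'   residual-based estimate.
#' @return A data frame with one row per testable set: `set_name`,
#'   `analysis_id`, `m` (members in the statistic universe), `direction`,
#'   `pvalue`, `fdr`, `vif`. Sets with fewer than two members in the
#'   universe are skipped with a warning and listed in the
#'   `skipped` attribute.
#' @export
camera_rank <- function(gene_stats, sets, residuals = NULL,
                        analysis_id = "analysis", fixed_rho = NULL) {
  stopifnot(is.numeric(gene_stats), !is.null(names(gene_stats)))
  universe <- toupper(names(gene_stats))
  names(gene_stats) <- universe
  G <- length(gene_stats)
  rows <- list()
  skipped <- character()
  for (s in sets) {
    members <- intersect(toupper(s$members), universe)
    m <- length(members)
    if (m < 2 || G - m < 2) {
      skipped <- c(skipped, s$name)
      next
    }
    if (!is.null(fixed_rho)) {
      rho <- fixed_rho
    } else {
      if (is.null(residuals))
        stop("residuals are required unless fixed_rho is given")
      R <- residuals[members, , drop = FALSE]
      cr <- stats::cor(t(R))
      rho <- mean(cr[upper.tri(cr)])
    }
    rho <- max(rho, 0)
    vif <- 1 + (m - 1) * rho
    in_set <- universe %in% members
    mean_in <- mean(gene_stats[in_set])
    mean_out <- mean(gene_stats[!in_set])
    s2 <- ((m - 1) * stats::var(gene_stats[in_set]) +
             (G - m - 1) * stats::var(gene_stats[!in_set])) / (G - 2)
    se <- sqrt(s2 * (vif / m + 1 / (G - m)))
    tstat <- (mean_in - mean_out) / se
    p <- 2 * stats::pt(-abs(tstat), df = G - 2)
    rows[[length(rows) + 1L]] <- data.frame(
      set_name = s$name, analysis_id = analysis_id, m = m,
      direction = if (mean_in >= 0) "Up" else "Down",
      pvalue = p, vif = vif, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped sets with < 2 members in the universe: ",
            paste(skipped, collapse = ", "))
  if (!length(rows)) {
    out <- data.frame(set_name = character(), analysis_id = character(),
                      m = integer(), direction = character(),
                      pvalue = numeric(), fdr = numeric(), vif = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$fdr <- bh_adjust(out$pvalue)
    out <- out[order(out$set_name), c("set_name", "analysis_id", "m",
                                      "direction", "pvalue", "fdr", "vif")]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Regulator-target overlap testing
#'
#' Upper-tail hypergeometric test of the overlap between each gene set and
#' each regulator's target list, all counts taken after intersection with
#' the statistic universe; this is a local replacement for a web-based
#' overlap service. Adjusted q-values are BH across all (set, regulator)
#' pairs. When DE tables are supplied, regulators significant in any of them
#' are flagged.
#'
#' @param sets Gene-set collection (candidate sets).
#' @param target_lists Gene-set collection of regulator target lists; each
#'   list's name is taken as the regulator's gene symbol.
#' @param universe Character vector of gene symbols defining the universe.
#' @param de_tables Optional named list of DE tables from [fit_de()] used to
#'   flag regulators that are themselves differentially expressed.
#' @return A data frame with `set_name`, `regulator`, `k`, `K`, `n`, `N`,
#'   `pvalue`, `qvalue`, and `regulator_de` (comma-separated analysis ids
#'   where the regulator is significant, or `""`).
#' @export
regulator_overlap <- function(sets, target_lists, universe,
                              de_tables = NULL) {
  if (!length(universe)) stop("universe must be non-empty")
  universe <- unique(toupper(universe))
  N <- length(universe)
  rows <- list()
  for (s in sets) {
    set_u <- intersect(toupper(s$members), universe)
    n <- length(set_u)
    for (tl in target_lists) {
      targ_u <- intersect(toupper(tl$members), universe)
      K <- length(targ_u)
      k <- length(intersect(set_u, targ_u))
      stopifnot(k <= min(K, n))  # counting bug guard
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        set_name = s$name, regulator = toupper(tl$name), k = k, K = K,
        n = n, N = N, pvalue = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$qvalue <- bh_adjust(out$pvalue)
  out$regulator_de <- ""
  if (!is.null(de_tables)) {
    for (i in seq_len(nrow(out))) {
      hits <- vapply(de_tables, function(de) {
        j <- match(out$regulator[i], de$gene_id)
        !is.na(j) && de$direction[j] != "ns"
      }, logical(1))
      out$regulator_de[i] <- paste(names(de_tables)[hits], collapse = ",")
    }
  }
  out <- out[order(out$set_name, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}
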