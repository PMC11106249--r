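#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - xhat_i) / (n - 1)` with
#' `xhat_i = x_i / max_j x_j`: 0 for perfectly ubiquitous expression, 1 for
#' expression confined to a single tissue.
#'
#' @param expr Nonnegative per-tissue expression vector of length >= 2.
#'   Callers working on log-CPM must clip negative values to zero first.
#' @return Tau in `[0, 1]`, or `NA` (with a warning) for an all-zero vector.
#' @export
tau <- function(expr) {
  if (!is.numeric(expr) || length(expr) < 2)
    stop("expr must be a numeric vector of length >= 2")
  if (any(is.na(expr))) stop("expr must not contain missing values")
  if (any(expr < 0))
    stop("expr must be nonnegative; clip log-scale values at zero first")
  mx <- max(expr)
  if (mx == 0) {
    warning("tau undefined for an all-zero expression vector")
    return(NA_real_)
  }
  sum(1 - expr / mx) / (length(expr) - 1)
}

#' Strict and relaxed tissue-specificity lists for one taxon
#'
#' Computes tau per gene on the grouped log-CPM profile (clipped below at
#' zero, so the zero-count sentinel reads as no expression), then assigns:
#' a single `strict_tissue` (the argmax; lexicographically first on ties)
#' when `tau >= tau_strict`, and the set of `relaxed_tissues` whose relative
#' expression reaches `relaxed_assign_frac` of the maximum when
#' `tau >= tau_relaxed`. Genes whose assignment (at either threshold)
#' includes a within-species control tissue are flagged `control_specific`.
#'
#' @param lcpm Long table from [grouped_lcpm()] for a single taxon.
#' @param cfg An [analysis_config()].
#' @param control_tissues Tissue labels counting as within-species controls
#'   (skin/bone/cartilage unrelated to cranial appendages).
#' @return A data frame with `gene_id`, `taxon`, `tau`, `strict_tissue`
#'   (`NA` when below threshold), `relaxed_tissues` (comma-separated, `""`
#'   when below threshold) and `control_specific`. Genes with no expression
#'   in any tissue after clipping are excluded and listed in the
#'   `excluded` attribute.
#' @export
specificity_lists <- function(lcpm, cfg = analysis_config(),
                              control_tissues = c("skin", "bone",
                                                  "cartilage_control")) {
  m <- lcpm_matrix(lcpm)
  if (anyNA(m))
    stop("grouped LCPM is incomplete: every gene needs a value per tissue")
  m <- pmax(m, 0)
  taxon <- unique(lcpm$taxon)
  stopifnot(length(taxon) == 1)
  rows <- vector("list", nrow(m))
  excluded <- character()
  tissues <- colnames(m)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (max(x) == 0) {
      excluded <- c(excluded, rownames(m)[i])
      next
    }
    tv <- sum(1 - x / max(x)) / (length(x) - 1)
    xhat <- x / max(x)
    strict_tissue <- NA_character_
    relaxed <- character()
    if (tv >= cfg$tau_strict)
      strict_tissue <- tissues[which(xhat == 1)][1]  # lexicographic: columns sorted
    if (tv >= cfg$tau_relaxed)
      relaxed <- tissues[xhat >= cfg$relaxed_assign_frac]
    assigned <- unique(c(strict_tissue[!is.na(strict_tissue)], relaxed))
    rows[[i]] <- data.frame(
      gene_id = rownames(m)[i], taxon = taxon, tau = tv,
      strict_tissue = strict_tissue,
      relaxed_tissues = paste(relaxed, collapse = ","),
      control_specific = any(assigned %in% control_tissues),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), taxon = character(),
                      tau = numeric(), strict_tissue = character(),
                      relaxed_tissues = character(),
                      control_specific = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (length(excluded))
    attr(out, "excluded") <- data.frame(gene_id = excluded,
                                        reason = "no expression after clipping",
                                        stringsAsFactors = FALSE)
  out
}
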