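#' Specify a test-tissue-versus-somatic-controls analysis
#'
#' @param analysis_id Short identifier for the analysis (e.g.
#'   `"horn_2mo"`, `"pedicle"`).
#' @param test_tissues Tissue labels pooled as the test group and contrasted
#'   against the pooled somatic control organs.
#' @param covariates Subset of metadata columns (`age`, `sex`, `species`)
#'   entered as fixed-effect factors. Each must vary across the included
#'   samples and must not be collinear with the test/control indicator;
#'   violations are an error, never silently dropped.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(analysis_id, test_tissues,
                        covariates = character()) {
  stopifnot(is.character(analysis_id), length(analysis_id) == 1,
            is.character(test_tissues), length(test_tissues) >= 1)
  bad <- setdiff(covariates, c("age", "sex", "species"))
  if (length(bad)) stop("unsupported covariates: ", paste(bad, collapse = ", "))
  structure(list(analysis_id = analysis_id, test_tissues = test_tissues,
                 covariates = covariates), class = "design_spec")
}

build_design_matrix <- function(meta, covariates) {
  group <- factor(ifelse(meta$role == "somatic", "somatic", "test"),
                  levels = c("somatic", "test"))
  df <- data.frame(group = group)
  X <- stats::model.matrix(~group, df)
  for (cv in covariates) {
    v <- factor(meta[[cv]])
    if (nlevels(v) < 2)
      stop("covariate '", cv, "' does not vary across the included samples")
    df[[cv]] <- v
    X2 <- stats::model.matrix(stats::as.formula(
      paste("~", paste(colnames(df), collapse = "+"))), df)
    if (qr(X2)$rank < ncol(X2))
      stop("covariate '", cv, "' is collinear with the design ",
           "(e.g. confounded with the test/control indicator); ",
           "remove it from the model")
    X <- X2
  }
  X
}

#' Fit the negative-binomial model for one test-versus-somatic contrast
#'
#' Fits gene-wise negative-binomial generalized linear models with edgeR:
#' offsets are the log TMM effective library sizes; gene-wise dispersions
#' are estimated by adjusted profile likelihood and shrunk toward an
#' abundance trend with robust empirical Bayes; the pooled-test-tissue
#' coefficient is tested with the quasi-likelihood F-test and p-values are
#' BH-adjusted within the analysis.
#'
#' @param cm A filtered [count_matrix()].
#' @param meta Validated metadata for `cm`.
#' @param nf Normalization factors from [tmm_factors()].
#' @param design A [design_spec()].
#' @param cfg An [analysis_config()].
#' @return A data frame (one row per gene): `gene_id`, `analysis_id`,
#'   `log2fc`, `pvalue`, `fdr`, and `direction` (`up`/`down` when
#'   `fdr < fdr_alpha`, else `ns`).
#' @export
fit_de <- function(cm, meta, nf, design, cfg = analysis_config()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(design, "design_spec"))
  meta <- validate_meta(meta, sample_ids = cm$sample_ids)
  missing_t <- setdiff(design$test_tissues, meta$tissue)
  if (length(missing_t))
    stop("test tissues absent from metadata: ",
         paste(missing_t, collapse = ", "))
  sel <- meta$tissue %in% design$test_tissues | meta$role == "somatic"
  meta <- meta[sel, , drop = FALSE]
  counts <- cm$counts[, sel, drop = FALSE]
  n_test <- sum(meta$role != "somatic")
  n_ctl <- sum(meta$role == "somatic")
  if (n_test < 2 || n_ctl < 2)
    stop("each of the test and somatic groups needs at least 2 replicates")
  X <- build_design_matrix(meta, design$covariates)

  nf_idx <- match(meta$sample_id, nf$sample_id)
  if (anyNA(nf_idx))
    stop("normalization factors missing for samples: ",
         paste(meta$sample_id[is.na(nf_idx)], collapse = ", "))
  f <- nf$tmm_factor[nf_idx]
  f <- f / exp(mean(log(f)))  # re-center the subset; offsets shift by a constant only
  d <- edgeR::DGEList(counts = counts,
                      lib.size = cm$library_sizes[sel],
                      norm.factors = f)
  d <- edgeR::estimateDisp(d, X, robust = TRUE)
  fit <- edgeR::glmQLFit(d, X, robust = TRUE)
  test <- edgeR::glmQLFTest(fit, coef = "grouptest")
  tab <- test$table
  fdr <- bh_adjust(tab$PValue)
  direction <- ifelse(fdr < cfg$fdr_alpha & tab$logFC > 0, "up",
                      ifelse(fdr < cfg$fdr_alpha & tab$logFC < 0, "down",
                             "ns"))
  res <- data.frame(gene_id = rownames(tab),
                    analysis_id = design$analysis_id,
                    log2fc = tab$logFC, pvalue = tab$PValue, fdr = fdr,
                    direction = direction, stringsAsFactors = FALSE)
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dispersion") <- data.frame(
    gene_id = rownames(d$counts), trended = d$trended.dispersion,
    tagwise = d$tagwise.dispersion, stringsAsFactors = FALSE)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at one), in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Combined-age and separate-age appendage models
#'
#' Runs the pooled-appendage analysis once with all appendage samples as a
#' single test tissue (age and sex covariates) and once per appendage tissue
#' with the sex covariate only (each appendage tissue here corresponds to a
#' single age, so an age term would be collinear with the tissue indicator).
#' A gene whose effect reverses between ages averages out in the combined
#' model, which is the conservative behavior intended for age-robust calls.
#'
#' @param cm A filtered [count_matrix()] for the taxon.
#' @param meta Validated metadata for `cm`.
#' @param nf Normalization factors.
#' @param cfg An [analysis_config()].
#' @param combined_id Analysis id for the pooled model.
#' @return A list with `combined` (one DE table) and `separate` (a named
#'   list of DE tables, one per appendage tissue).
#' @export
combined_vs_separate <- function(cm, meta, nf, cfg = analysis_config(),
                                 combined_id = "horn_combined") {
  meta_v <- validate_meta(meta, sample_ids = cm$sample_ids)
  app <- sort(unique(meta_v$tissue[meta_v$role == "appendage"]))
  if (!length(app)) stop("no appendage samples in this dataset")
  combined <- fit_de(cm, meta_v, nf,
                     design_spec(combined_id, app, c("age", "sex")), cfg)
  separate <- lapply(app, function(ti)
    fit_de(cm, meta_v, nf, design_spec(ti, ti, "sex"), cfg))
  names(separate) <- app
  list(combined = combined, separate = separate)
}

#' Per-gene standardized statistics from a DE table
#'
#' Signed normal quantiles, `sign(log2fc) * qnorm(1 - p/2)`, suitable as the
#' gene-level statistic for competitive gene-set ranking.
#'
#' @param de A DE table from [fit_de()].
#' @return Named numeric vector (names are gene ids).
#' @export
de_zscores <- function(de) {
  p <- pmin(pmax(de$pvalue, 1e-300), 1)
  z <- sign(de$log2fc) * stats::qnorm(p / 2, lower.tail = FALSE)
  stats::setNames(z, de$gene_id)
}

#' Residual log-CPM matrix for a design
#'
#' Log2 counts per million (0.5 prior count, TMM effective library sizes)
#' with the design-matrix fit removed by least squares; used to estimate
#' inter-gene correlations for the competitive gene-set test.
#'
#' @inheritParams fit_de
#' @return Numeric matrix, genes by included samples.
#' @export
lcpm_residuals <- function(cm, meta, nf, design, cfg = analysis_config()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(design, "design_spec"))
  meta <- validate_meta(meta, sample_ids = cm$sample_ids)
  sel <- meta$tissue %in% design$test_tissues | meta$role == "somatic"
  meta <- meta[sel, , drop = FALSE]
  eff <- nf$effective_libsize[match(meta$sample_id, nf$sample_id)]
  E <- log2(t(t(cm$counts[, sel, drop = FALSE] + 0.5) / eff) * 1e6)
  X <- build_design_matrix(meta, design$covariates)
  qx <- qr(X)
  t(stats::qr.resid(qx, t(E)))
}
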