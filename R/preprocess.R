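#' Filter genes by expression level
#'
#' Keeps a gene if (a) there is at least one tissue in which every sample of
#' that tissue reaches `cpm_min` counts per million and (b) its summed CPM
#' across all samples reaches `cpm_total_min`. CPM here is computed from raw
#' library sizes (the filter runs before TMM normalization). All boundaries
#' are inclusive (`>=`).
#'
#' @param cm A [count_matrix()].
#' @param meta Validated sample metadata aligned to `cm` (the `tissue`
#'   column defines the within-tissue groups; each somatic organ is its own
#'   tissue here).
#' @param cfg An [analysis_config()].
#' @return A [count_matrix()] restricted to the kept genes. Library sizes
#'   are deliberately kept from the full matrix: filtering genes does not
#'   change sequencing depth, so downstream CPM continues to use the
#'   original library sizes.
#' @export
filter_by_expression <- function(cm, meta, cfg = analysis_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  meta <- validate_meta(meta, sample_ids = cm$sample_ids)
  cpm <- t(t(cm$counts) / cm$library_sizes) * 1e6
  tissues <- split(seq_along(cm$sample_ids), meta$tissue)
  in_tissue <- vapply(tissues, function(idx)
    apply(cpm[, idx, drop = FALSE] >= cfg$cpm_min, 1, all), logical(nrow(cpm)))
  keep <- apply(in_tissue, 1, any) & rowSums(cpm) >= cfg$cpm_total_min
  if (!any(keep))
    warning("no genes pass the expression filter")
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  out$gene_ids <- rownames(out$counts)
  out
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors for between-sample
#' normalization, computed with edgeR's implementation of the published
#' method: the reference sample is the one whose 75th-percentile CPM is
#' closest to the mean 75th percentile; per-gene log ratios against the
#' reference are trimmed 30 percent on M and 5 percent on A; the factor is
#' two to the precision-weighted mean of the remaining M values
#' (inverse binomial delta-method variances as weights); factors are
#' rescaled to geometric mean one.
#'
#' @param cm A [count_matrix()] with at least two samples.
#' @return A data frame with `sample_id`, `tmm_factor` and
#'   `effective_libsize` (library size times factor).
#' @export
tmm_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(cm$sample_ids) < 2)
    stop("TMM normalization needs at least two samples")
  f <- edgeR::calcNormFactors(cm$counts, lib.size = cm$library_sizes,
                              method = "TMM")
  if (any(!is.finite(f))) {
    bad <- cm$sample_ids[!is.finite(f)]
    stop("TMM factor undefined for sample(s) sharing no positive genes ",
         "with the reference: ", paste(bad, collapse = ", "))
  }
  data.frame(sample_id = cm$sample_ids,
             tmm_factor = unname(f),
             effective_libsize = unname(cm$library_sizes * f),
             stringsAsFactors = FALSE)
}

#' Grouped log2 counts per million with a zero-count sentinel
#'
#' Summarizes expression per (gene, tissue) group:
#' `lcpm = log2((sum counts + 0.5) / sum effective library size * 1e6)` when
#' the group's summed raw count is positive, and exactly the configured
#' sentinel (default -21) when it is zero, so downstream stages can treat
#' sentinel entries as unobserved. Genes are retained only if, in at least
#' one tissue, at least two-thirds of the replicates have a raw count of 10
#' or more (inclusive boundary).
#'
#' @param cm A [count_matrix()].
#' @param meta Validated metadata aligned to `cm`.
#' @param nf Normalization factors from [tmm_factors()].
#' @param cfg An [analysis_config()].
#' @return A long data frame with `gene_id`, `taxon`, `tissue`, `lcpm`.
#' @export
grouped_lcpm <- function(cm, meta, nf, cfg = analysis_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  meta <- validate_meta(meta, sample_ids = cm$sample_ids)
  missing_nf <- setdiff(cm$sample_ids, nf$sample_id)
  if (length(missing_nf))
    stop("normalization factors missing for samples: ",
         paste(missing_nf, collapse = ", "))
  eff <- nf$effective_libsize[match(cm$sample_ids, nf$sample_id)]
  if (any(eff <= 0)) stop("non-positive effective library size")
  tissues <- split(seq_along(cm$sample_ids), meta$tissue)

  keep_tab <- vapply(tissues, function(idx) {
    reps <- length(idx)
    rowSums(cm$counts[, idx, drop = FALSE] >= 10) >= (2 / 3) * reps
  }, logical(nrow(cm$counts)))
  keep <- apply(keep_tab, 1, any)
  genes <- cm$gene_ids[keep]

  taxon <- unique(meta$taxon)
  if (length(taxon) != 1)
    stop("grouped_lcpm expects samples from a single taxon")
  res <- lapply(names(tissues), function(ti) {
    idx <- tissues[[ti]]
    s <- rowSums(cm$counts[keep, idx, drop = FALSE])
    L <- sum(eff[idx])
    if (L == 0) stop("zero total library size in tissue group '", ti, "'")
    lcpm <- ifelse(s == 0, cfg$lcpm_zero_sentinel,
                   log2((s + 0.5) / L * 1e6))
    data.frame(gene_id = genes, taxon = taxon, tissue = ti, lcpm = lcpm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene_id, out$tissue), , drop = FALSE]
}

#' Reshape a grouped LCPM table to a gene-by-tissue matrix
#'
#' @param lcpm A long table from [grouped_lcpm()].
#' @return A numeric matrix, genes in rows, tissues in columns.
#' @export
lcpm_matrix <- function(lcpm) {
  genes <- sort(unique(lcpm$gene_id))
  tissues <- sort(unique(lcpm$tissue))
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(match(lcpm$gene_id, genes), match(lcpm$tissue, tissues))] <-
    lcpm$lcpm
  m
}
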