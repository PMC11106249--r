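#' Analysis configuration
#'
#' Central container for the thresholds and tuning parameters used across the
#' pipeline: the expression filter, the BH false-discovery-rate cutoff, the
#' tau specificity thresholds, the grouped log-CPM zero sentinel, and the
#' self-organizing-map / k-medoid clustering controls.
#'
#' @param fdr_alpha BH false discovery rate cutoff for significance calls.
#' @param cpm_min Minimum counts-per-million a gene must reach in every
#'   sample of at least one tissue to pass the expression filter.
#' @param cpm_total_min Minimum summed CPM across all samples.
#' @param tau_strict Tau threshold for the strict (single-tissue)
#'   specificity list.
#' @param tau_relaxed Tau threshold for the relaxed specificity list.
#' @param relaxed_assign_frac Fraction of the maximum tissue expression at or
#'   above which a tissue is included in a relaxed multi-tissue assignment.
#' @param lcpm_zero_sentinel Value recorded for a (gene, tissue) group whose
#'   summed raw count is zero.
#' @param som_rows,som_cols Self-organizing-map grid dimensions.
#' @param som_epochs Number of passes over the data during SOM training.
#' @param som_alpha_start,som_alpha_end Linearly declining learning rate.
#' @param kmedoid_k_max Largest cluster count considered by the gap statistic.
#' @param gap_B Number of uniform reference datasets for the gap statistic.
#' @param rng_seed Seed used by stages with internal randomness.
#'
#' @return An object of class `appendhom_config` (a validated list).
#' @export
analysis_config <- function(fdr_alpha = 0.05,
                            cpm_min = 10,
                            cpm_total_min = 15,
                            tau_strict = 0.9,
                            tau_relaxed = 0.75,
                            relaxed_assign_frac = 0.75,
                            lcpm_zero_sentinel = -21,
                            som_rows = 20,
                            som_cols = 20,
                            som_epochs = 100,
                            som_alpha_start = 0.05,
                            som_alpha_end = 0.01,
                            kmedoid_k_max = 8,
                            gap_B = 50,
                            rng_seed = 1L) {
  cfg <- list(fdr_alpha = fdr_alpha, cpm_min = cpm_min,
              cpm_total_min = cpm_total_min, tau_strict = tau_strict,
              tau_relaxed = tau_relaxed,
              relaxed_assign_frac = relaxed_assign_frac,
              lcpm_zero_sentinel = lcpm_zero_sentinel,
              som_rows = as.integer(som_rows), som_cols = as.integer(som_cols),
              som_epochs = as.integer(som_epochs),
              som_alpha_start = som_alpha_start,
              som_alpha_end = som_alpha_end,
              kmedoid_k_max = as.integer(kmedoid_k_max),
              gap_B = as.integer(gap_B),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  class(cfg) <- "appendhom_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$fdr_alpha), length(cfg$fdr_alpha) == 1)
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1)
    stop("fdr_alpha must lie strictly between 0 and 1")
  if (!(cfg$tau_relaxed > 0 && cfg$tau_relaxed < cfg$tau_strict &&
        cfg$tau_strict <= 1))
    stop("tau thresholds must satisfy 0 < tau_relaxed < tau_strict <= 1")
  if (cfg$som_rows < 2 && cfg$som_rows != 1)
    stop("som_rows must be >= 2 (or 1 for a degenerate map)")
  if (cfg$som_cols < 2 && cfg$som_cols != 1)
    stop("som_cols must be >= 2 (or 1 for a degenerate map)")
  if (cfg$cpm_min < 0 || cfg$cpm_total_min < 0)
    stop("CPM thresholds must be nonnegative")
  if (cfg$relaxed_assign_frac <= 0 || cfg$relaxed_assign_frac > 1)
    stop("relaxed_assign_frac must lie in (0, 1]")
  invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Unknown fields are an error so that typos in configuration files do not
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file whose keys are [analysis_config()]
#'   arguments.
#' @return An `appendhom_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.appendhom_config <- function(x, ...) {
  cat("appendhom analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
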