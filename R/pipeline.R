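#' Run the full homology-assessment pipeline
#'
#' Chains, per taxon: expression filtering, TMM normalization, grouped
#' log-CPM, the test-tissue-versus-pooled-somatic DE analyses (for the
#' horn-bearing ingroup both a combined-age model and per-age models),
#' within-species distinctness filtering, outgroup-conditioned homology
#' calls, tau specificity with strict and relaxed homology lists,
#' shared-proportion tables, and (optionally) the SOM/k-medoid clustering
#' summary.
#'
#' @param datasets Named list with one entry per taxon (as produced by
#'   [simulate_dataset()]`$datasets`): each a list with `counts` (a
#'   [count_matrix()]) and `meta`. Exactly one taxon must have role
#'   `ingroup_a`, one `ingroup_b`, one `outgroup`.
#' @param cfg An [analysis_config()].
#' @param covariates Named list of covariate sets per taxon for the control
#'   and non-horn test analyses; covariates must vary in every analysis
#'   they enter.
#' @param run_som Whether to train the SOM and summarize its clusters.
#' @param report_path Optional path for the JSON report.
#' @return A list with `de` (named DE tables per taxon), `profiles`,
#'   `calls` (per evidence mode), `proportions` (per mode), `tau` tables,
#'   `lcpm` tables, `som` (model + cluster summary or `NULL`) and
#'   `report`.
#' @export
run_pipeline <- function(datasets, cfg = analysis_config(),
                         covariates = list(ingroup_a = c("age", "sex"),
                                           ingroup_b = c("sex", "species"),
                                           outgroup = "sex"),
                         run_som = FALSE, report_path = NULL) {
  roles <- vapply(datasets, function(d)
    unique(validate_meta(d$meta)$taxon), "")
  if (!setequal(roles, c("ingroup_a", "ingroup_b", "outgroup")))
    stop("datasets must contain exactly one ingroup_a, one ingroup_b ",
         "and one outgroup taxon")
  by_role <- stats::setNames(names(roles), roles)

  stage <- lapply(names(datasets), function(tx) {
    cm <- datasets[[tx]]$counts
    meta <- validate_meta(datasets[[tx]]$meta, sample_ids = cm$sample_ids)
    filtered <- filter_by_expression(cm, meta, cfg)
    nf <- tmm_factors(filtered)
    lcpm <- grouped_lcpm(cm, meta, nf, cfg)
    role <- unique(meta$taxon)
    covs <- covariates[[role]]
    app <- sort(unique(meta$tissue[meta$role == "appendage"]))
    ctl <- sort(unique(meta$tissue[meta$role == "control"]))
    de <- list()
    if (length(app)) {
      if (role == "ingroup_a") {
        cs <- combined_vs_separate(filtered, meta, nf, cfg)
        de <- c(list(horn_combined = cs$combined), cs$separate)
      } else {
        de <- lapply(app, function(ti)
          fit_de(filtered, meta, nf, design_spec(ti, ti, covs), cfg))
        names(de) <- app
      }
    }
    ctl_de <- lapply(ctl, function(ti)
      fit_de(filtered, meta, nf, design_spec(ti, ti, covs), cfg))
    names(ctl_de) <- ctl
    list(role = role, filtered = filtered, meta = meta, nf = nf,
         lcpm = lcpm, appendage = app, controls = ctl,
         de_test = de, de_control = ctl_de)
  })
  names(stage) <- names(datasets)

  sa <- stage[[by_role["ingroup_a"]]]
  sb <- stage[[by_role["ingroup_b"]]]
  so <- stage[[by_role["outgroup"]]]

  prof_a <- within_species_distinct(sa$de_test, sa$de_control)
  prof_b <- within_species_distinct(sb$de_test, sb$de_control)
  outgroup_tables <- so$de_control
  de_calls <- call_homology(prof_a, prof_b, outgroup_tables, mode = "de")

  tau_tabs <- lapply(stage, function(s)
    specificity_lists(s$lcpm, cfg, control_tissues = s$controls))
  tau_strict <- tau_homology(tau_tabs[[by_role["ingroup_a"]]],
                             tau_tabs[[by_role["ingroup_b"]]],
                             tau_tabs[[by_role["outgroup"]]],
                             "strict", sa$appendage, sb$appendage,
                             outgroup_tissues = so$controls)
  tau_relaxed <- tau_homology(tau_tabs[[by_role["ingroup_a"]]],
                              tau_tabs[[by_role["ingroup_b"]]],
                              tau_tabs[[by_role["outgroup"]]],
                              "relaxed", sa$appendage, sb$appendage,
                              outgroup_tissues = so$controls)

  calls <- list(de = de_calls, tau_strict = tau_strict,
                tau_relaxed = tau_relaxed)
  horn_analyses <- names(sa$de_test)
  proportions <- list(
    de = shared_proportions(de_calls, horn_analyses, sb$appendage),
    tau_strict = shared_proportions(tau_strict, sa$appendage, sb$appendage),
    tau_relaxed = shared_proportions(tau_relaxed, sa$appendage,
                                     sb$appendage))

  som <- NULL
  if (run_som) {
    all_de <- c(sa$de_test, sa$de_control, sb$de_test, sb$de_control,
                so$de_control)
    genes <- som_input_genes(all_de)
    lcpm_tables <- lapply(stage, `[[`, "lcpm")
    profiles <- merge_lcpm_profiles(lcpm_tables, genes)
    if (nrow(profiles) >= 10) {
      model <- train_som(profiles, cfg, seed = cfg$rng_seed)
      model <- assign_unit_clusters(model, cfg)
      merged <- do.call(rbind, lapply(names(lcpm_tables), function(tx) {
        l <- lcpm_tables[[tx]]
        l$tissue <- paste(tx, l$tissue, sep = ".")
        l
      }))
      som <- list(model = model,
                  summary = cluster_summaries(model, merged, cfg))
    }
  }

  report <- build_report(calls, proportions,
                         cluster_summary = if (!is.null(som)) som$summary,
                         path = report_path)
  list(stage = stage, profiles = list(ingroup_a = prof_a, ingroup_b = prof_b),
       calls = calls, proportions = proportions, tau = tau_tabs,
       som = som, report = report)
}

#' Score homology calls against simulation truth
#'
#' @param calls A homology-call table (usually the `de` mode).
#' @param truth The `truth` table from [simulate_dataset()].
#' @return A list with `sensitivity` (planted homologous-appendage genes
#'   recovered as homologous), `specificity_skin_shared` and
#'   `specificity_outgroup_shared` (planted confounder classes correctly
#'   not called homologous), and `false_calls` (null genes called
#'   homologous).
#' @export
score_against_truth <- function(calls, truth) {
  hom_genes <- calls$gene_id[calls$status == "homologous"]
  of_class <- function(cl) truth$gene_id[truth$class == cl]
  prop_in <- function(g) if (length(g)) mean(g %in% hom_genes) else NA_real_
  list(sensitivity = prop_in(of_class("homologous_appendage")),
       specificity_skin_shared = 1 - prop_in(of_class("skin_shared")),
       specificity_outgroup_shared = 1 - prop_in(of_class("bone_program")),
       specificity_taxon_specific = 1 - prop_in(of_class("taxon_specific")),
       false_calls = sum(of_class("null") %in% hom_genes))
}
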