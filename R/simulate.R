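#' Simulation configuration
#'
#' Parameters for the three-taxon negative-binomial count simulator. The
#' generator emulates the study layout: two ingroups bearing cranial
#' appendages (a bovid-like taxon with two horn-bud ages plus a skin control,
#' and a cervid-like taxon with seven antler tissues plus skin and bone
#' controls), one outgroup without appendages (skin, cartilage and bone
#' controls), and the six pooled somatic control organs in every taxon.
#'
#' @param n_genes Number of simulated genes.
#' @param replicates_per_tissue Biological replicates for each appendage and
#'   control tissue (at least 3).
#' @param somatic_replicates Replicates per somatic organ. The six organs are
#'   pooled into a single reference group for differential expression, so one
#'   sample per organ already gives a six-sample reference.
#' @param baseline_log2_mean_range Range of baseline gene abundance on the
#'   log2 counts-per-million scale. The default (0, 12) makes 2000 genes sum
#'   to roughly one million CPM units, so baselines read directly as CPM.
#' @param de_baseline_log2_range Baseline range for genes carrying planted
#'   differential-expression signal; restricted to clearly expressed levels
#'   so truth classes describe genes the expression filter retains.
#' @param specific_baseline_log2_range Low off-target baseline for
#'   tissue-specific genes (tau near 1 requires near-zero log expression in
#'   non-target tissues).
#' @param dispersion_range Range of the gene-wise NB dispersion phi, drawn
#'   log-uniformly (variance mu + phi * mu^2).
#' @param libsize_factor_range Per-sample library scaling factors, drawn
#'   log-uniformly.
#' @param base_libsize Nominal sequencing depth multiplied by the factors.
#' @param effect_log2fc Planted log2 fold change magnitude.
#' @param class_proportions Named fractions for the planted gene classes
#'   `homologous_appendage`, `skin_shared`, `bone_program`, `taxon_specific`
#'   and `tissue_specific`; the remainder are null genes. Counts use
#'   `floor(n_genes * proportion)`.
#' @param target_tau Realized tau (on expected log-CPM) targeted for
#'   tissue-specific genes.
#' @param covariate_effects Optional named list of additive log2 shifts,
#'   e.g. `list(sex = 0.5)`, applied to every tenth gene in samples at the
#'   second level of that covariate.
#' @param rng_seed Master seed. Gene-level truth is drawn under the master
#'   seed; each taxon's counts are drawn from its own stream derived from it,
#'   so adding a taxon never perturbs another taxon's counts.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       replicates_per_tissue = 3,
                       somatic_replicates = 1,
                       baseline_log2_mean_range = c(0, 12),
                       de_baseline_log2_range = c(3, 10),
                       specific_baseline_log2_range = c(0.2, 0.8),
                       dispersion_range = c(0.05, 0.4),
                       libsize_factor_range = c(0.5, 2),
                       base_libsize = 2e7,
                       effect_log2fc = 2,
                       class_proportions = c(homologous_appendage = 0.05,
                                             skin_shared = 0.05,
                                             bone_program = 0.05,
                                             taxon_specific = 0.05,
                                             tissue_specific = 0.05),
                       target_tau = 0.95,
                       covariate_effects = NULL,
                       rng_seed = 1L) {
  if (replicates_per_tissue < 3)
    stop("replicates_per_tissue must be at least 3")
  if (sum(class_proportions) > 1)
    stop("class proportions must sum to at most 1")
  if (any(class_proportions < 0))
    stop("class proportions must be nonnegative")
  known <- c("homologous_appendage", "skin_shared", "bone_program",
             "taxon_specific", "tissue_specific")
  bad <- setdiff(names(class_proportions), known)
  if (length(bad)) stop("unknown gene classes: ", paste(bad, collapse = ", "))
  stopifnot(diff(baseline_log2_mean_range) >= 0,
            all(dispersion_range > 0), all(libsize_factor_range > 0),
            base_libsize > 0, target_tau > 0, target_tau < 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Tissue layout used by the simulator
#'
#' @return A list with one entry per taxon (`cattle`, `deer`, `pig`) giving
#'   the canonical taxon role, the tissues and their roles.
#' @export
default_tissue_layout <- function() {
  list(
    cattle = list(
      taxon = "ingroup_a",
      tissues = c(horn_bud_2mo = "appendage", horn_bud_4mo = "appendage",
                  skin = "control",
                  stats::setNames(rep("somatic", 6), SOMATIC_ORGANS))),
    deer = list(
      taxon = "ingroup_b",
      tissues = c(pedicle = "appendage", antler_tip = "appendage",
                  mineralized_cartilage = "appendage",
                  cartilage_zone = "appendage", transition_zone = "appendage",
                  pre_cartilage = "appendage",
                  reserve_mesenchyme = "appendage",
                  skin = "control", bone = "control",
                  stats::setNames(rep("somatic", 6), SOMATIC_ORGANS))),
    pig = list(
      taxon = "outgroup",
      tissues = c(skin = "control", cartilage_control = "control",
                  bone = "control",
                  stats::setNames(rep("somatic", 6), SOMATIC_ORGANS))))
}

sim_gene_classes <- function(cfg) {
  classes <- rep("null", cfg$n_genes)
  idx <- 1L
  for (cl in names(cfg$class_proportions)) {
    k <- floor(cfg$n_genes * cfg$class_proportions[[cl]])
    if (k > 0) {
      classes[idx:(idx + k - 1L)] <- cl
      idx <- idx + k
    }
  }
  classes
}

# Bisect the log2 enrichment of the target tissue until tau computed on the
# expected clipped log2-CPM profile hits the target.
calibrate_enrichment <- function(base_lcpm, target_idx, target_tau,
                                 tol = 0.005) {
  f <- function(le) {
    v <- base_lcpm
    v[target_idx] <- v[target_idx] + le
    tau(pmax(v, 0))
  }
  lo <- 0; hi <- 60
  if (f(hi) < target_tau) return(hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (abs(f(mid) - target_tau) < tol) return(mid)
    if (f(mid) < target_tau) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

sim_ages <- function(taxon_name, tissue, n) {
  if (taxon_name == "cattle") {
    if (tissue == "horn_bud_2mo") return(rep("2mo", n))
    if (tissue == "horn_bud_4mo") return(rep("4mo", n))
    return(rep(c("2mo", "4mo", "adult"), length.out = n))
  }
  if (taxon_name == "deer")
    return(rep(c("yearling", "adult", "aged"), length.out = n))
  rep(c("juvenile", "adult"), length.out = n)
}

sim_species <- function(taxon_name, n) {
  if (taxon_name == "deer")
    return(rep(c("cervus_nippon", "capreolus_capreolus",
                 "odocoileus_virginianus"), length.out = n))
  rep(c(cattle = "bos_taurus", pig = "sus_scrofa")[taxon_name], n)
}

#' Simulate a three-taxon count dataset with known truth
#'
#' Counts are drawn from a negative binomial with mean
#' `mu = baseline * tissue-effect * library-factor` and variance
#' `mu + phi * mu^2`. Planted classes: `homologous_appendage` genes are
#' shifted by `effect_log2fc` in the appendage tissues of both ingroups and
#' nowhere else; `skin_shared` genes are shifted in the appendage tissues and
#' the skin control of each ingroup (same direction); `bone_program` genes
#' carry a conserved osteogenic signal in the appendage tissues of both
#' ingroups and in the outgroup bone and cartilage, so only the outgroup
#' comparison can exclude them; `taxon_specific` genes are shifted in the
#' appendage tissues of a single ingroup; `tissue_specific` genes receive a
#' multiplicative enrichment in one randomly chosen non-somatic tissue,
#' calibrated by bisection so their tau on expected log-CPM hits
#' `target_tau`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `datasets` (per taxon: `counts`, a [count_matrix()],
#'   and `meta`), `truth` (per-gene class, direction, planted tissues and
#'   target tau) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  layout <- default_tissue_layout()
  set.seed(cfg$rng_seed)

  n <- cfg$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))
  classes <- sim_gene_classes(cfg)
  baseline <- stats::runif(n, cfg$baseline_log2_mean_range[1],
                           cfg$baseline_log2_mean_range[2])
  de_classes <- c("homologous_appendage", "skin_shared", "bone_program",
                  "taxon_specific")
  is_de <- classes %in% de_classes
  baseline[is_de] <- stats::runif(sum(is_de), cfg$de_baseline_log2_range[1],
                                  cfg$de_baseline_log2_range[2])
  is_ts <- classes == "tissue_specific"
  baseline[is_ts] <- stats::runif(sum(is_ts),
                                  cfg$specific_baseline_log2_range[1],
                                  cfg$specific_baseline_log2_range[2])
  # express baselines exactly on the log2-CPM scale: non-specific genes
  # carry the grand total to one million CPM units
  scale_idx <- !is_ts
  baseline[scale_idx] <- baseline[scale_idx] +
    log2((1e6 - sum(2^baseline[is_ts])) / sum(2^baseline[scale_idx]))
  dispersion <- exp(stats::runif(n, log(cfg$dispersion_range[1]),
                                 log(cfg$dispersion_range[2])))
  direction <- ifelse(stats::runif(n) < 0.5, "up", "down")
  direction[classes == "null"] <- NA
  own_ingroup <- rep(c("cattle", "deer"), length.out = n)

  appendage_of <- lapply(layout, function(l)
    names(l$tissues)[l$tissues == "appendage"])
  nonsomatic_of <- lapply(layout, function(l)
    names(l$tissues)[l$tissues != "somatic"])

  # planted (taxon, tissue) sets per gene
  planted <- vector("list", n)
  ts_taxon <- rep(NA_character_, n)
  ts_tissue <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "homologous_appendage") {
      planted[[i]] <- c(paste0("cattle:", appendage_of$cattle),
                        paste0("deer:", appendage_of$deer))
    } else if (cl == "skin_shared") {
      planted[[i]] <- c(paste0("cattle:", c(appendage_of$cattle, "skin")),
                        paste0("deer:", c(appendage_of$deer, "skin")))
    } else if (cl == "bone_program") {
      planted[[i]] <- c(paste0("cattle:", appendage_of$cattle),
                        paste0("deer:", appendage_of$deer),
                        "pig:bone", "pig:cartilage_control")
    } else if (cl == "taxon_specific") {
      tx <- own_ingroup[i]
      planted[[i]] <- paste0(tx, ":", appendage_of[[tx]])
    } else if (cl == "tissue_specific") {
      tx <- sample(names(layout), 1)
      ti <- sample(nonsomatic_of[[tx]], 1)
      ts_taxon[i] <- tx
      ts_tissue[i] <- ti
      planted[[i]] <- paste0(tx, ":", ti)
    } else {
      planted[[i]] <- character()
    }
  }

  # optional covariate shifts hit every 10th gene
  cov_genes <- seq_len(n) %% 10L == 0L

  # per-taxon log2 shift matrices and count draws
  datasets <- list()
  enrichment <- rep(NA_real_, n)
  for (tix in seq_along(layout)) {
    tname <- names(layout)[tix]
    lay <- layout[[tix]]
    tissues <- names(lay$tissues)
    roles <- unname(lay$tissues)
    shift <- matrix(0, n, length(tissues),
                    dimnames = list(gene_ids, tissues))
    for (i in which(classes %in% de_classes)) {
      keys <- planted[[i]]
      here <- sub("^[^:]+:", "", keys[startsWith(keys, paste0(tname, ":"))])
      if (length(here))
        shift[i, here] <- if (direction[i] == "up") cfg$effect_log2fc else
          -cfg$effect_log2fc
    }
    # calibrate tissue-specific enrichment against the expected
    # post-normalization log-CPM: realized CPM is the baseline relative to
    # the whole dataset's expected output per tissue
    tissue_total <- colSums(2^(baseline + shift))
    for (i in which(is_ts)) {
      if (!identical(ts_taxon[i], tname)) next
      base_vec <- baseline[i] + log2(1e6) - log2(tissue_total)
      le <- calibrate_enrichment(base_vec, match(ts_tissue[i], tissues),
                                 cfg$target_tau)
      enrichment[i] <- le
      shift[i, ts_tissue[i]] <- le
    }

    nrep <- ifelse(roles == "somatic", cfg$somatic_replicates,
                   cfg$replicates_per_tissue)
    tissue_vec <- rep(tissues, nrep)
    role_vec <- rep(roles, nrep)
    rep_vec <- unlist(lapply(nrep, seq_len))
    sample_ids <- sprintf("%s_%s_r%d", tname, tissue_vec, rep_vec)
    ns <- length(sample_ids)
    # covariates cycle over the global sample index so that single-replicate
    # somatic organs still vary in age/sex and no level coincides with a
    # single tissue indicator
    age_pool <- unique(sim_ages(tname, "somatic", 3))
    ages <- age_pool[(seq_len(ns) - 1L) %% length(age_pool) + 1L]
    ages[tissue_vec == "horn_bud_2mo"] <- "2mo"
    ages[tissue_vec == "horn_bud_4mo"] <- "4mo"
    meta <- data.frame(sample_id = sample_ids, taxon = lay$taxon,
                       tissue = tissue_vec, role = role_vec,
                       age = ages,
                       sex = rep(c("female", "male"), length.out = ns),
                       species = sim_species(tname, ns),
                       replicate = rep_vec,
                       stringsAsFactors = FALSE)

    set.seed((cfg$rng_seed %% 100000L) * 131L + tix)
    libfac <- exp(stats::runif(ns, log(cfg$libsize_factor_range[1]),
                               log(cfg$libsize_factor_range[2])))
    lib <- cfg$base_libsize * libfac
    lcpm_mean <- baseline + shift[, tissue_vec, drop = FALSE]
    if (!is.null(cfg$covariate_effects)) {
      for (cv in names(cfg$covariate_effects)) {
        eff <- cfg$covariate_effects[[cv]]
        if (eff == 0) next
        lev <- sort(unique(meta[[cv]]))
        if (length(lev) < 2) next
        hit <- meta[[cv]] == lev[2]
        lcpm_mean[cov_genes, hit] <- lcpm_mean[cov_genes, hit] + eff
      }
    }
    mu <- 2^lcpm_mean * rep(lib / 1e6, each = n)
    counts <- matrix(stats::rnbinom(n * ns, mu = mu,
                                    size = rep(1 / dispersion, ns)),
                     nrow = n, dimnames = list(gene_ids, sample_ids))
    datasets[[tname]] <- list(counts = count_matrix(counts), meta = meta)
  }

  truth <- data.frame(
    gene_id = gene_ids,
    class = classes,
    planted_direction = direction,
    planted_tissues = vapply(planted, paste, "", collapse = ","),
    target_tau = ifelse(is_ts, cfg$target_tau, NA_real_),
    enrichment_log2 = enrichment,
    baseline_log2_cpm = baseline,
    dispersion = dispersion,
    stringsAsFactors = FALSE)

  list(datasets = datasets, truth = truth, config = cfg)
}
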