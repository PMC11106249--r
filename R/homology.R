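#' Directions of evidence for a set of genes
#'
#' @param de A DE table from [fit_de()].
#' @param genes Gene universe; genes absent from the table are `absent`
#'   (filtered out of that analysis), which is distinct from `ns`.
#' @return Character vector over `genes` in `{up, down, ns, absent}`.
#' @export
de_directions <- function(de, genes) {
  v <- de$direction[match(genes, de$gene_id)]
  v[is.na(v)] <- "absent"
  v
}

#' Within-species distinctness filter
#'
#' A gene keeps its signal for an appendage analysis only if it is
#' significant there and, in every within-species control analysis
#' (skin/bone unrelated to the appendage), it is either not significant or
#' significant in the opposite direction. Same-direction significance in a
#' control removes the signal and is recorded. Opposite-direction control
#' significance is retained and flagged (this is how a gene underexpressed
#' in appendages but overexpressed in normal bone stays testable).
#'
#' @param tests Named list of DE tables for the taxon's appendage analyses.
#' @param controls Named list of DE tables for the taxon's within-species
#'   control tissues.
#' @param required_controls Control names that must be present (e.g. the
#'   cervid analysis requires both `skin` and `bone`); defaults to the names
#'   supplied.
#' @return An evidence-profile data frame: `gene_id` plus one column per
#'   test analysis with values in `{up, down, ns, absent}` after control
#'   filtering. Attributes: `exclusions` (gene, analysis, control removed
#'   by) and `control_flags` (gene, control, opposite-direction note).
#' @export
within_species_distinct <- function(tests, controls,
                                    required_controls = names(controls)) {
  if (!length(tests)) stop("no test analyses supplied")
  missing_ctl <- setdiff(required_controls, names(controls))
  if (length(missing_ctl))
    stop("missing within-species control table(s): ",
         paste(missing_ctl, collapse = ", "))
  genes <- sort(unique(unlist(lapply(c(tests, controls), `[[`, "gene_id"))))
  ctl_dir <- vapply(controls, de_directions, character(length(genes)),
                    genes = genes)
  ctl_dir <- matrix(ctl_dir, nrow = length(genes),
                    dimnames = list(genes, names(controls)))
  prof <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  exclusions <- list()
  flags <- list()
  for (an in names(tests)) {
    dir <- de_directions(tests[[an]], genes)
    for (ctl in names(controls)) {
      same <- dir %in% c("up", "down") & ctl_dir[, ctl] == dir
      if (any(same)) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          gene_id = genes[same], analysis_id = an, control = ctl,
          reason = "excluded_within_species_control",
          stringsAsFactors = FALSE)
        dir[same] <- "ns"
      }
      opp <- dir %in% c("up", "down") & ctl_dir[, ctl] %in% c("up", "down") &
        ctl_dir[, ctl] != dir
      if (any(opp))
        flags[[length(flags) + 1L]] <- data.frame(
          gene_id = genes[opp], control = ctl,
          flag = paste0("opposite_direction_in_", ctl),
          stringsAsFactors = FALSE)
    }
    prof[[an]] <- dir
  }
  attr(prof, "exclusions") <- if (length(exclusions))
    unique(do.call(rbind, exclusions)) else NULL
  attr(prof, "control_flags") <- if (length(flags))
    unique(do.call(rbind, flags)) else NULL
  prof
}

#' Outgroup-conditioned homology calls from evidence profiles
#'
#' A gene is called homologous when some appendage analysis in each ingroup
#' carries the same direction of significance (after the within-species
#' filter) and every outgroup analysis is not significant, absent, or
#' significant in the opposite direction. Same-direction significance in
#' any outgroup analysis excludes the gene; a signal confined to one
#' ingroup is `not_shared`; with no outgroup tables at all every candidate
#' is `untestable_missing_outgroup` — an outgroup is required before a
#' shared pattern can be read as shared-derived.
#'
#' @param profile_a,profile_b Evidence profiles from
#'   [within_species_distinct()] for the two ingroups.
#' @param outgroup Named list of DE tables for the outgroup analyses
#'   (skin/cartilage/bone); may be empty.
#' @param mode Evidence mode recorded in the output (default `"de"`).
#' @return A homology-call data frame: `gene_id`, `evidence_mode`,
#'   `shared_direction`, `horn_support`, `antler_support`
#'   (comma-separated analysis ids), `status`, `control_flags`.
#' @export
call_homology <- function(profile_a, profile_b, outgroup, mode = "de") {
  a_cols <- setdiff(names(profile_a), "gene_id")
  b_cols <- setdiff(names(profile_b), "gene_id")
  genes <- sort(intersect(profile_a$gene_id, profile_b$gene_id))
  a <- as.matrix(profile_a[match(genes, profile_a$gene_id), a_cols,
                           drop = FALSE])
  b <- as.matrix(profile_b[match(genes, profile_b$gene_id), b_cols,
                           drop = FALSE])
  out_dir <- if (length(outgroup))
    matrix(vapply(outgroup, de_directions, character(length(genes)),
                  genes = genes),
           nrow = length(genes), dimnames = list(genes, names(outgroup)))
  else NULL

  flags_a <- attr(profile_a, "control_flags")
  flags_b <- attr(profile_b, "control_flags")
  flag_of <- function(g) {
    f <- c(if (!is.null(flags_a)) flags_a$flag[flags_a$gene_id == g],
           if (!is.null(flags_b)) flags_b$flag[flags_b$gene_id == g])
    paste(sort(unique(f)), collapse = ",")
  }

  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    av <- a[i, ]; bv <- b[i, ]
    has_a <- any(av %in% c("up", "down"))
    has_b <- any(bv %in% c("up", "down"))
    if (!has_a && !has_b) next
    shared <- intersect(av[av %in% c("up", "down")],
                        bv[bv %in% c("up", "down")])
    if (!length(shared)) {
      rows[[i]] <- data.frame(gene_id = genes[i], evidence_mode = mode,
                              shared_direction = NA_character_,
                              horn_support = paste(a_cols[av %in% c("up", "down")],
                                                   collapse = ","),
                              antler_support = paste(b_cols[bv %in% c("up", "down")],
                                                     collapse = ","),
                              status = "not_shared", control_flags = flag_of(genes[i]),
                              stringsAsFactors = FALSE)
      next
    }
    # ambiguous both-direction sharing: larger total support wins, ties up
    if (length(shared) > 1) {
      support <- vapply(shared, function(dd) sum(av == dd) + sum(bv == dd),
                        numeric(1))
      shared <- shared[order(-support, match(shared, c("up", "down")))][1]
    }
    hs <- paste(a_cols[av == shared], collapse = ",")
    as_ <- paste(b_cols[bv == shared], collapse = ",")
    if (is.null(out_dir)) {
      status <- "untestable_missing_outgroup"
    } else if (any(out_dir[i, ] == shared)) {
      status <- "excluded_outgroup"
    } else {
      status <- "homologous"
    }
    rows[[i]] <- data.frame(gene_id = genes[i], evidence_mode = mode,
                            shared_direction = shared, horn_support = hs,
                            antler_support = as_, status = status,
                            control_flags = flag_of(genes[i]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), evidence_mode = character(),
                      shared_direction = character(),
                      horn_support = character(),
                      antler_support = character(), status = character(),
                      control_flags = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Homology calls from tissue-specificity lists
#'
#' Under the chosen threshold mode, a gene is homologous when it is specific
#' to at least one appendage tissue in both ingroups, not control-specific
#' in either ingroup (specific to within-species skin/bone/cartilage), and
#' not specific to any of the outgroup's non-somatic tissues at the same
#' threshold.
#'
#' @param tau_a,tau_b,tau_out Specificity tables from [specificity_lists()]
#'   for the two ingroups and the outgroup, computed under one
#'   configuration.
#' @param mode `"strict"` (single argmax tissue) or `"relaxed"`
#'   (multi-tissue assignment).
#' @param appendage_a,appendage_b Appendage tissue labels of each ingroup.
#' @param outgroup_tissues Outgroup tissue labels whose specificity excludes
#'   a gene (its skin/cartilage/bone controls).
#' @return A homology-call data frame as in [call_homology()], with
#'   `evidence_mode` `tau_strict` or `tau_relaxed`.
#' @export
tau_homology <- function(tau_a, tau_b, tau_out,
                         mode = c("strict", "relaxed"),
                         appendage_a, appendage_b,
                         outgroup_tissues = c("skin", "bone",
                                              "cartilage_control")) {
  mode <- match.arg(mode)
  assigned <- function(tt, g) {
    i <- match(g, tt$gene_id)
    if (is.na(i)) return(character())
    if (mode == "strict") {
      s <- tt$strict_tissue[i]
      if (is.na(s)) character() else s
    } else {
      r <- tt$relaxed_tissues[i]
      if (!nzchar(r)) character() else strsplit(r, ",", fixed = TRUE)[[1]]
    }
  }
  genes <- sort(unique(c(tau_a$gene_id, tau_b$gene_id)))
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    ta <- assigned(tau_a, g)
    tb <- assigned(tau_b, g)
    app_a <- intersect(ta, appendage_a)
    app_b <- intersect(tb, appendage_b)
    if (!length(app_a) && !length(app_b)) next
    ctl_a <- !is.na(match(g, tau_a$gene_id)) &&
      isTRUE(tau_a$control_specific[match(g, tau_a$gene_id)])
    ctl_b <- !is.na(match(g, tau_b$gene_id)) &&
      isTRUE(tau_b$control_specific[match(g, tau_b$gene_id)])
    if (ctl_a || ctl_b) {
      status <- "excluded_within_species_control"
    } else if (!length(app_a) || !length(app_b)) {
      status <- "not_shared"
    } else {
      to <- assigned(tau_out, g)
      status <- if (length(intersect(to, outgroup_tissues)))
        "excluded_outgroup" else "homologous"
    }
    rows[[i]] <- data.frame(
      gene_id = g, evidence_mode = paste0("tau_", mode),
      shared_direction = NA_character_,
      horn_support = paste(sort(app_a), collapse = ","),
      antler_support = paste(sort(app_b), collapse = ","),
      status = status, control_flags = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), evidence_mode = character(),
                      shared_direction = character(),
                      horn_support = character(),
                      antler_support = character(), status = character(),
                      control_flags = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Shared-proportion table between horn analyses and antler tissues
#'
#' For each horn analysis `h`, `total_h` is the number of homologous genes
#' supported by `h` (a gene supported by several horn analyses counts toward
#' each); the proportion for antler tissue `t` is the number of those genes
#' also supported by `t` divided by `total_h`.
#'
#' @param calls A homology-call table; only rows with status `homologous`
#'   are used.
#' @param horn_analyses Horn analysis ids (rows of the output).
#' @param antler_tissues Antler tissue labels (columns of the output).
#' @return A long data frame: `horn_analysis`, `antler_tissue`,
#'   `shared_count`, `total`, `proportion` (missing when `total` is zero).
#' @export
shared_proportions <- function(calls, horn_analyses, antler_tissues) {
  hom <- calls[calls$status == "homologous", , drop = FALSE]
  split_set <- function(v) strsplit(v, ",", fixed = TRUE)
  hs <- split_set(hom$horn_support)
  as_ <- split_set(hom$antler_support)
  out <- expand.grid(horn_analysis = horn_analyses,
                     antler_tissue = antler_tissues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$shared_count <- NA_integer_
  out$total <- NA_integer_
  out$proportion <- NA_real_
  for (i in seq_len(nrow(out))) {
    in_h <- vapply(hs, function(x) out$horn_analysis[i] %in% x, logical(1))
    total <- sum(in_h)
    shared <- sum(in_h & vapply(as_, function(x)
      out$antler_tissue[i] %in% x, logical(1)))
    out$shared_count[i] <- shared
    out$total[i] <- total
    out$proportion[i] <- if (total > 0) shared / total else NA_real_
  }
  out
}

#' Machine-readable summary report
#'
#' Collects per-mode homologous gene lists with their supporting tissues,
#' shared-proportion tables, gene-set homology with control flags, and SOM
#' cluster summaries into one deterministic structure; identical inputs
#' produce byte-identical JSON.
#'
#' @param homology Named list of homology-call tables (by evidence mode).
#' @param proportions Optional named list of [shared_proportions()] tables.
#' @param gene_sets Optional gene-set homology table.
#' @param cluster_summary Optional [cluster_summaries()] table.
#' @param path Optional output path for pretty-printed JSON.
#' @return The report as a list (invisibly when written to `path`).
#' @export
build_report <- function(homology, proportions = NULL, gene_sets = NULL,
                         cluster_summary = NULL, path = NULL) {
  if (!length(homology)) stop("at least one homology-call table is required")
  fmt_calls <- function(calls) {
    hom <- calls[calls$status == "homologous", , drop = FALSE]
    hom <- hom[order(hom$gene_id), , drop = FALSE]
    list(n_homologous = nrow(hom),
         genes = lapply(seq_len(nrow(hom)), function(i) list(
           gene_id = hom$gene_id[i],
           shared_direction = hom$shared_direction[i],
           horn_support = sort(strsplit(hom$horn_support[i], ",")[[1]]),
           antler_support = sort(strsplit(hom$antler_support[i], ",")[[1]]),
           control_flags = hom$control_flags[i])),
         status_counts = as.list(table(calls$status)))
  }
  report <- list(
    homology = lapply(homology[order(names(homology))], fmt_calls),
    proportions = if (!is.null(proportions))
      lapply(proportions[order(names(proportions))], function(p)
        p[order(p$horn_analysis, p$antler_tissue), , drop = FALSE]),
    gene_sets = gene_sets,
    som_clusters = cluster_summary)
  report <- report[!vapply(report, is.null, TRUE)]
  if (!is.null(path)) {
    json <- jsonlite::toJSON(report, pretty = TRUE, auto_unbox = TRUE,
                             digits = NA, na = "null")
    writeLines(json, path)
    return(invisible(report))
  }
  report
}
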