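#' @importFrom utils read.delim write.table
NULL

#' The six pooled somatic control organs
#'
#' Non-appendage organs used as the pooled reference group in every
#' within-species differential expression analysis.
#' @export
SOMATIC_ORGANS <- c("muscle", "kidney", "heart", "liver", "spleen", "lung")

TAXON_LEVELS <- c("ingroup_a", "ingroup_b", "outgroup")
TAXON_ALIASES <- c(cattle = "ingroup_a", deer = "ingroup_b", pig = "outgroup")
ROLE_LEVELS <- c("appendage", "control", "somatic")
META_COLUMNS <- c("sample_id", "taxon", "tissue", "role", "age", "sex",
                  "species", "replicate")

#' Construct a validated count matrix
#'
#' @param counts Nonnegative integer matrix, genes in rows, samples in
#'   columns. Row names are gene symbols (stored uppercase so symbols match
#'   across genome annotations), column names are sample ids.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_ids`, `sample_ids` and `library_sizes` (exact column sums).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (any(is.na(counts)))
    stop("counts must not contain missing values")
  if (any(counts < 0))
    stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  rownames(counts) <- toupper(rownames(counts))
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicated gene ids: ", paste(unique(dup), collapse = ", "))
  obj <- list(counts = counts,
              gene_ids = rownames(counts),
              sample_ids = colnames(counts),
              library_sizes = colSums(counts))
  class(obj) <- "count_matrix"
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (median library size %s)\n",
              length(x$gene_ids), length(x$sample_ids),
              format(stats::median(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param x A `count_matrix`.
#' @param genes,samples Character vectors of ids (or logical/integer
#'   indices); `NULL` keeps everything. Library sizes are recomputed.
#' @return A `count_matrix`.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  count_matrix(m)
}

validate_meta <- function(meta, sample_ids = NULL) {
  missing_cols <- setdiff(META_COLUMNS, names(meta))
  if (length(missing_cols))
    stop("metadata is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  meta$taxon <- as.character(meta$taxon)
  alias <- meta$taxon %in% names(TAXON_ALIASES)
  meta$taxon[alias] <- TAXON_ALIASES[meta$taxon[alias]]
  bad_tax <- setdiff(unique(meta$taxon), TAXON_LEVELS)
  if (length(bad_tax))
    stop("unknown taxon labels: ", paste(bad_tax, collapse = ", "),
         " (expected ", paste(TAXON_LEVELS, collapse = "/"),
         " or aliases cattle/deer/pig)")
  bad_role <- setdiff(unique(meta$role), ROLE_LEVELS)
  if (length(bad_role))
    stop("unknown role labels: ", paste(bad_role, collapse = ", "))
  som <- meta$role == "somatic"
  bad_organ <- setdiff(unique(meta$tissue[som]), SOMATIC_ORGANS)
  if (length(bad_organ))
    stop("somatic samples must come from the six-organ list (",
         paste(SOMATIC_ORGANS, collapse = ", "), "); found: ",
         paste(bad_organ, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample ids in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, meta$sample_id)
    if (length(absent))
      stop("samples present in counts but missing from metadata: ",
           paste(absent, collapse = ", "))
    meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Read a count matrix and its sample metadata
#'
#' The counts file is UTF-8, tab-separated, unquoted, with the gene symbol in
#' the first column and one column per sample. The metadata file is
#' tab-separated with columns `sample_id`, `taxon`, `tissue`, `role`, `age`,
#' `sex`, `species` and `replicate`. Metadata rows are reordered to match the
#' counts columns, so loading is insensitive to metadata row order.
#'
#' @param path Path to the counts TSV.
#' @param meta_path Path to the metadata TSV.
#' @return A list with elements `counts` (a [count_matrix()]) and `meta`
#'   (a validated data frame aligned to the counts columns).
#' @export
read_counts <- function(path, meta_path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("counts file must have a gene column and at least one sample column")
  genes <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v) || any(is.na(v)) || any(abs(v - round(v)) > 1e-8)) {
      bad <- which(!grepl("^[0-9]+$", as.character(v)))[1]
      stop(sprintf("non-integer count at row %d (gene %s), column '%s'",
                   bad, genes[bad], names(mat)[j]))
    }
  }
  mat <- as.matrix(mat)
  rownames(mat) <- genes
  cm <- count_matrix(mat)
  meta <- read.delim(meta_path, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
  meta <- validate_meta(meta, sample_ids = cm$sample_ids)
  list(counts = cm, meta = meta)
}

#' Read a GMT gene-set collection
#'
#' One gene set per line: name, description, then one or more member symbols,
#' tab-separated. Members are deduplicated and uppercased so symbols match
#' across annotations.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets, each a list with `name`, `description`
#'   and `members` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields", i))
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT parse error at line %d: gene set has no members", i))
    sets[[i]] <- list(name = fields[1], description = fields[2],
                      members = members)
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets A named list as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Write a result table deterministically
#'
#' Tables are written tab-separated, unquoted, with `NA` for missing values.
#' Rows are ordered by gene id, then by any of the usual grouping columns
#' (`taxon`, `tissue`, `analysis_id`, `set_name`, `cluster_id`) that are
#' present, so that a write/read round trip is the identity and repeated runs
#' produce byte-identical files.
#'
#' @param records A data frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("records must be non-null")
  records <- as.data.frame(records)
  keys <- intersect(c("gene_id", "gene", "set_name", "cluster_id",
                      "analysis_id", "taxon", "tissue", "horn_analysis",
                      "antler_tissue", "sample_id"), names(records))
  if (length(keys) && nrow(records))
    records <- records[do.call(order, records[keys]), , drop = FALSE]
  ok <- tryCatch({
    write.table(records, path, sep = "\t", quote = FALSE, na = "NA",
                row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("could not write table to '", path, "': ",
                              conditionMessage(e)))
  invisible(ok)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A data frame with `NA` restored for missing values.
#' @export
read_result_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             na.strings = "NA", stringsAsFactors = FALSE)
}
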