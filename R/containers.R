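#' Construct a clade-by-sample read count table
#'
#' The central container for 16S phylotype data: a non-negative integer
#' matrix of read counts with full lineage strings as row names and sample
#' IDs as column names, plus per-sample metadata (subject, body site,
#' visit number).
#'
#' @param counts Numeric matrix, clades in rows (row names = lineage
#'   strings), samples in columns (column names = sample IDs). Entries must
#'   be non-negative integers.
#' @param meta `data.frame` with columns `sample_id`, `subject_id`,
#'   `body_site`, `visit`; one row per sample of `counts`.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `clade_counts`: a list with elements
#'   `counts`, `taxonomy` (lineage, name, rank per row) and `meta`.
#' @export
clade_counts <- function(counts, meta, validate = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (validate) {
    if (is.null(rownames(counts)) && nrow(counts) > 0L)
      stop("counts must have lineage strings as row names")
    if (is.null(colnames(counts)) && ncol(counts) > 0L)
      stop("counts must have sample IDs as column names")
    if (any(counts < 0)) stop("negative read counts are not allowed")
    if (any(counts != round(counts))) stop("read counts must be integers")
    if (anyDuplicated(colnames(counts))) stop("duplicated sample IDs")
    req <- c("sample_id", "subject_id", "body_site", "visit")
    miss <- setdiff(req, names(meta))
    if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
    absent <- setdiff(colnames(counts), meta$sample_id)
    if (length(absent))
      stop("samples without metadata: ", paste(utils::head(absent, 5), collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(counts = counts,
         taxonomy = taxonomy_frame(rownames(counts)),
         meta = meta),
    class = "clade_counts"
  )
}

#' @export
print.clade_counts <- function(x, ...) {
  cat(sprintf("<clade_counts> %d clades x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (isTRUE(attr(x, "propagated"))) " (propagated)" else ""))
  tab <- table(x$taxonomy$rank)
  cat("  ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a per-rank relative abundance table
#'
#' Usually produced by [normalize_abundance()]; rarely called directly.
#' Within each sample and each taxonomic rank, abundances over that rank's
#' clades sum to one.
#'
#' @param ab Numeric matrix in `[0, 1]`, same layout as [clade_counts()].
#' @param meta Per-sample metadata as in [clade_counts()].
#' @return An object of class `clade_abundance`.
#' @export
clade_abundance <- function(ab, meta) {
  ab <- as.matrix(ab)
  structure(
    list(ab = ab,
         taxonomy = taxonomy_frame(rownames(ab)),
         meta = meta[match(colnames(ab), meta$sample_id), , drop = FALSE]),
    class = "clade_abundance"
  )
}

#' @export
print.clade_abundance <- function(x, ...) {
  cat(sprintf("<clade_abundance> %d clades x %d samples\n",
              nrow(x$ab), ncol(x$ab)))
  invisible(x)
}

#' Extract the abundance (or count) matrix at one taxonomic rank
#'
#' @param x A `clade_counts` or `clade_abundance` object.
#' @param rank One of [tract_ranks()], or `"deepest"` for the finest rank
#'   present in the table.
#' @return Numeric matrix restricted to rows of that rank.
#' @export
at_rank <- function(x, rank = "genus") {
  mat <- if (inherits(x, "clade_counts")) x$counts else x$ab
  present <- intersect(tract_ranks(), unique(x$taxonomy$rank))
  if (identical(rank, "deepest")) rank <- present[length(present)]
  if (!rank %in% tract_ranks()) stop("unknown rank: ", rank)
  mat[x$taxonomy$rank == rank, , drop = FALSE]
}

#' Read a clade count table and its sample metadata from TSV files
#'
#' The count file carries full lineage strings in the first column and one
#' integer column per sample, matching the layout of deposited digestive
#' tract phylotype tables. The metadata file has columns `sample_id`,
#' `subject_id`, `body_site`, `visit`.
#'
#' @param counts_file Path to the counts TSV.
#' @param meta_file Path to the metadata TSV.
#' @param lineage_sep Delimiter inside lineage strings (`"|"` or `";"`).
#' @return A [clade_counts()] object.
#' @export
read_clade_counts <- function(counts_file, meta_file, lineage_sep = "|") {
  raw <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  lin <- as.character(raw[[1]])
  if (lineage_sep != "|") lin <- gsub(lineage_sep, "|", lin, fixed = TRUE)
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- lin
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  clade_counts(counts, meta)
}

#' Write a clade count table and its metadata to TSV files
#'
#' @param x A [clade_counts()] object.
#' @param counts_file,meta_file Output paths.
#' @return `x`, invisibly.
#' @export
write_clade_counts <- function(x, counts_file, meta_file) {
  df <- data.frame(lineage = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
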