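#' Taxonomic ranks used throughout the package
#'
#' The six RDP-style ranks at which clade abundances are analysed, from the
#' bacterial root down to genus. Species-level resolution is deliberately
#' absent: short-read 16S phylotyping does not support reliable species
#' identification, so genus is the finest rank carried by any table.
#'
#' @return Character vector of rank names, coarsest first.
#' @export
tract_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

UNCLASSIFIED <- "unclassified"

#' Parse an RDP-style lineage string into a clade
#'
#' Lineage strings name the full ancestry of a clade from the bacterial
#' root, e.g. `"Bacteria|Firmicutes|Bacilli|Lactobacillales|Streptococcaceae|Streptococcus"`.
#' Empty trailing fields (reads that could not be assigned deeper) become
#' `"unclassified"` placeholder nodes, so
#' `"Bacteria|Bacteroidetes|||"` parses to an order-rank placeholder under an
#' unclassified class within the Bacteroidetes.
#'
#' @param x A single lineage string.
#' @param sep Field delimiter, `"|"` (default) or `";"`.
#' @return An object of class `tract_clade` with elements `name`, `rank` and
#'   `lineage` (ancestor names from the root, excluding the clade itself).
#' @examples
#' parse_lineage("Bacteria|Firmicutes|Bacilli|Lactobacillales|Streptococcaceae|Streptococcus")
#' @export
parse_lineage <- function(x, sep = "|") {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) stop("empty lineage string")
  if (!sep %in% c("|", ";")) stop("lineage delimiter must be '|' or ';'")
  parts <- split_keep_trailing(x, sep)[[1]]
  ranks <- tract_ranks()
  if (length(parts) > length(ranks)) {
    stop(sprintf("malformed lineage (depth %d exceeds %d levels): '%s'",
                 length(parts), length(ranks), x))
  }
  parts <- trimws(parts)
  parts[!nzchar(parts)] <- UNCLASSIFIED
  structure(
    list(name = parts[length(parts)],
         rank = ranks[length(parts)],
         lineage = if (length(parts) > 1L) parts[-length(parts)] else character()),
    class = "tract_clade"
  )
}

#' Serialize a clade back to its lineage string
#'
#' Inverse of [parse_lineage()] for well-formed paths.
#'
#' @param clade A `tract_clade` object.
#' @param sep Field delimiter.
#' @return The full lineage string.
#' @export
lineage_string <- function(clade, sep = "|") {
  stopifnot(inherits(clade, "tract_clade"))
  paste(c(clade$lineage, clade$name), collapse = sep)
}

#' @export
print.tract_clade <- function(x, ...) {
  cat(sprintf("<clade> %s [%s]\n", x$name, x$rank))
  invisible(x)
}

# strsplit drops trailing empty fields; lineage strings use them as
# unclassified placeholders, so they must survive the split
split_keep_trailing <- function(x, sep) {
  lapply(strsplit(paste0(x, sep, "\r"), sep, fixed = TRUE),
         function(p) p[-length(p)])
}

# Split a vector of lineage strings into a character matrix padded with NA.
split_lineages <- function(lineages, sep = "|") {
  ranks <- tract_ranks()
  if (length(lineages) == 0L) {
    return(matrix(NA_character_, 0L, length(ranks)))
  }
  parts <- split_keep_trailing(lineages, sep)
  depth <- lengths(parts)
  bad <- which(depth > length(ranks))
  if (length(bad)) {
    stop(sprintf("malformed lineage (depth exceeds %d levels): '%s'",
                 length(ranks), lineages[bad[1]]))
  }
  mat <- matrix(NA_character_, nrow = length(parts), ncol = length(ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p[!nzchar(p)] <- UNCLASSIFIED
    mat[i, seq_along(p)] <- p
  }
  mat
}

# Taxonomy frame (one row per clade) derived from row lineage strings.
taxonomy_frame <- function(lineages, sep = "|") {
  if (is.null(lineages) || length(lineages) == 0L) {
    return(data.frame(lineage = character(), name = character(),
                      rank = character(), stringsAsFactors = FALSE))
  }
  mat <- split_lineages(lineages, sep)
  depth <- rowSums(!is.na(mat))
  data.frame(
    lineage = lineages,
    name = mat[cbind(seq_along(lineages), depth)],
    rank = tract_ranks()[depth],
    stringsAsFactors = FALSE
  )
}

#' Propagate read counts up the taxonomic hierarchy
#'
#' Takes a count table whose rows are the clades reads were assigned to
#' (typically genus-level lineages, possibly truncated where classification
#' stopped early) and produces a table with one row per clade at every rank
#' from domain to genus. Each internal clade's count is the sum of the reads
#' assigned to it directly plus all of its descendants. Reads assigned above
#' genus level are carried down through `"unclassified"` placeholder nodes,
#' so the column sum at every rank equals the sample's total assigned reads.
#'
#' Applying the function to an already-propagated table is a no-op.
#'
#' @param x A [clade_counts()] table.
#' @return A `clade_counts` table with rows at all six ranks, ordered by
#'   rank then lineage.
#' @export
propagate_counts <- function(x) {
  stopifnot(inherits(x, "clade_counts"))
  if (isTRUE(attr(x, "propagated"))) return(x)
  ranks <- tract_ranks()
  if (nrow(x$counts) == 0L) {
    out <- x
    attr(out, "propagated") <- TRUE
    return(out)
  }
  mat <- split_lineages(rownames(x$counts))
  # extend truncated assignments to genus depth with placeholders
  mat[is.na(mat)] <- UNCLASSIFIED
  blocks <- vector("list", length(ranks))
  for (d in seq_along(ranks)) {
    key <- apply(mat[, seq_len(d), drop = FALSE], 1L, paste, collapse = "|")
    agg <- rowsum(x$counts, group = key, reorder = TRUE)
    blocks[[d]] <- agg
  }
  counts <- do.call(rbind, blocks)
  out <- clade_counts(counts, x$meta, validate = TRUE)
  attr(out, "propagated") <- TRUE
  out
}
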