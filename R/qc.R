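#' Remove taxa without minimal read support across the dataset
#'
#' A clade is retained only when it is supported, in the whole dataset, by
#' at least `min_reads` sequences in at least `min_samples` samples. Two
#' readings of this rule are implemented:
#' \describe{
#'   \item{`"per_sample"` (default, stricter)}{at least `min_samples`
#'     distinct samples must each contain `min_reads` or more reads of the
#'     clade.}
#'   \item{`"total"`}{the clade must appear in at least `min_samples`
#'     samples and carry at least `min_reads` reads in total.}
#' }
#' Counts of removed clades are dropped, not reassigned.
#'
#' @param x A propagated [clade_counts()] table.
#' @param min_reads,min_samples Support thresholds (default 2 and 2).
#' @param rule Which reading of the support rule to apply.
#' @return List with elements `counts` (filtered table) and `report`
#'   (a `qc_report`).
#' @export
filter_unsupported_taxa <- function(x, min_reads = 2, min_samples = 2,
                                    rule = c("per_sample", "total")) {
  stopifnot(inherits(x, "clade_counts"))
  rule <- match.arg(rule)
  keep <- if (rule == "per_sample") {
    rowSums(x$counts >= min_reads) >= min_samples
  } else {
    rowSums(x$counts > 0) >= min_samples & rowSums(x$counts) >= min_reads
  }
  removed <- x$taxonomy[!keep, c("lineage", "rank"), drop = FALSE]
  out <- clade_counts(x$counts[keep, , drop = FALSE], x$meta, validate = FALSE)
  out$taxonomy <- x$taxonomy[keep, , drop = FALSE]
  attr(out, "propagated") <- attr(x, "propagated")
  list(counts = out, report = qc_report(removed_taxa = removed))
}

#' Remove low-coverage samples
#'
#' For each sample, the read count of its most abundant taxon `t` is
#' compared with the highest count that the same taxon `t` achieves in any
#' sample of the dataset. If the former is less than `fraction` (default
#' 1%) of the latter, the sample is judged under-sequenced and discarded.
#' The most abundant taxon is evaluated at `rank` (default the finest
#' classified rank available), since comparing raw counts across ranks
#' would be meaningless.
#'
#' @param x A [clade_counts()] table (taxon filter already applied).
#' @param fraction Coverage threshold as a fraction of the taxon's dataset
#'   maximum; discarding uses a strict `<` comparison.
#' @param rank Rank at which "most abundant taxon" is determined.
#' @return List with `counts` (filtered table) and `report`.
#' @export
filter_low_coverage_samples <- function(x, fraction = 0.01, rank = "deepest") {
  stopifnot(inherits(x, "clade_counts"))
  m <- at_rank(x, rank)
  if (nrow(m) == 0L) stop("no clades at the requested rank")
  drop <- logical(ncol(m))
  for (s in seq_len(ncol(m))) {
    top <- which.max(m[, s])
    c_s <- m[top, s]
    if (c_s == 0) { drop[s] <- TRUE; next }
    C <- max(m[top, ])
    drop[s] <- c_s < fraction * C
  }
  removed <- data.frame(sample_id = colnames(m)[drop],
                        reason = rep("low_coverage", sum(drop)),
                        stringsAsFactors = FALSE)
  keep_ids <- colnames(m)[!drop]
  out <- subset_samples_counts(x, keep_ids)
  list(counts = out, report = qc_report(removed_samples = removed))
}

#' Keep only each subject's earliest visit per body site
#'
#' Repeat visits resample the same community and would pseudo-replicate
#' subjects, so for every (subject, body site) pair only the sample with
#' the minimum visit number is retained. The minimum visit present is used
#' rather than literally visit 1, to tolerate cohorts whose first
#' time-point failed QC.
#'
#' @param x A [clade_counts()] table with visit metadata.
#' @return List with `counts` (filtered table) and `report`.
#' @export
keep_first_visit <- function(x) {
  stopifnot(inherits(x, "clade_counts"))
  meta <- x$meta
  key <- paste(meta$subject_id, meta$body_site, meta$visit, sep = "\r")
  if (anyDuplicated(key))
    stop("ambiguous samples: duplicated (subject, body_site, visit) triples")
  grp <- paste(meta$subject_id, meta$body_site, sep = "\r")
  min_visit <- stats::ave(meta$visit, grp, FUN = min)
  drop <- meta$visit != min_visit
  removed <- data.frame(sample_id = meta$sample_id[drop],
                        reason = rep("repeat_visit", sum(drop)),
                        stringsAsFactors = FALSE)
  out <- subset_samples_counts(x, meta$sample_id[!drop])
  list(counts = out, report = qc_report(removed_samples = removed))
}

#' Normalize read counts to per-rank relative abundances
#'
#' Within every sample and every taxonomic rank, counts are divided by the
#' sample's total over that rank's clades, so abundances at each rank sum
#' to one. Normalization happens after all filtering, so abundances are
#' relative to retained taxa.
#'
#' @param x A [clade_counts()] table, QC complete.
#' @return A [clade_abundance()] object with the same rows.
#' @export
normalize_abundance <- function(x) {
  stopifnot(inherits(x, "clade_counts"))
  ab <- x$counts
  for (r in intersect(tract_ranks(), unique(x$taxonomy$rank))) {
    idx <- x$taxonomy$rank == r
    tot <- colSums(x$counts[idx, , drop = FALSE])
    if (any(tot == 0))
      stop(sprintf("sample(s) with zero total at rank %s: %s", r,
                   paste(utils::head(colnames(x$counts)[tot == 0], 5),
                         collapse = ", ")))
    ab[idx, ] <- sweep(x$counts[idx, , drop = FALSE], 2L, tot, "/")
  }
  out <- clade_abundance(ab, x$meta)
  out$taxonomy <- x$taxonomy
  out
}

#' Run the full post-processing and QC pipeline
#'
#' Fixed order: count propagation through the taxonomy, dataset-level taxon
#' support filter, low-coverage sample filter, first-visit deduplication,
#' and per-rank normalization. Re-running the pipeline on its own retained
#' counts changes nothing.
#'
#' @param x A [clade_counts()] table of raw assigned counts.
#' @inheritParams filter_unsupported_taxa
#' @inheritParams filter_low_coverage_samples
#' @return List with `counts` (retained, propagated), `abundance`
#'   (normalized) and `report` (merged `qc_report`).
#' @export
qc_pipeline <- function(x, min_reads = 2, min_samples = 2,
                        rule = "per_sample", fraction = 0.01,
                        rank = "deepest") {
  x <- propagate_counts(x)
  s1 <- filter_unsupported_taxa(x, min_reads, min_samples, rule)
  s2 <- filter_low_coverage_samples(s1$counts, fraction, rank)
  s3 <- keep_first_visit(s2$counts)
  report <- merge_qc_reports(list(s1$report, s2$report, s3$report),
                             retained_taxa = nrow(s3$counts$counts),
                             retained_samples = ncol(s3$counts$counts))
  list(counts = s3$counts,
       abundance = normalize_abundance(s3$counts),
       report = report)
}

qc_report <- function(removed_taxa = NULL, removed_samples = NULL,
                      retained_taxa = NA_integer_,
                      retained_samples = NA_integer_) {
  if (is.null(removed_taxa))
    removed_taxa <- data.frame(lineage = character(), rank = character(),
                               stringsAsFactors = FALSE)
  if (is.null(removed_samples))
    removed_samples <- data.frame(sample_id = character(), reason = character(),
                                  stringsAsFactors = FALSE)
  structure(list(removed_taxa = removed_taxa,
                 removed_samples = removed_samples,
                 retained_taxa = retained_taxa,
                 retained_samples = retained_samples),
            class = "qc_report")
}

merge_qc_reports <- function(reports, retained_taxa, retained_samples) {
  qc_report(
    removed_taxa = do.call(rbind, lapply(reports, `[[`, "removed_taxa")),
    removed_samples = do.call(rbind, lapply(reports, `[[`, "removed_samples")),
    retained_taxa = retained_taxa,
    retained_samples = retained_samples
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> removed %d taxa, %d samples; retained %s taxa, %s samples\n",
              nrow(x$removed_taxa), nrow(x$removed_samples),
              x$retained_taxa, x$retained_samples))
  if (nrow(x$removed_samples))
    print(table(x$removed_samples$reason))
  invisible(x)
}

# sample subsetting that keeps taxonomy/propagation attributes intact
subset_samples_counts <- function(x, sample_ids) {
  out <- clade_counts(x$counts[, sample_ids, drop = FALSE],
                      x$meta[x$meta$sample_id %in% sample_ids, , drop = FALSE],
                      validate = FALSE)
  out$taxonomy <- x$taxonomy
  attr(out, "propagated") <- attr(x, "propagated")
  out
}
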