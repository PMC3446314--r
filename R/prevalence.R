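#' Body sites of the upper digestive tract
#'
#' The nine non-stool habitats (all oral/oropharyngeal sites).
#' @return Character vector of body-site codes.
#' @export
upper_tract_sites <- function() {
  setdiff(names(site_groups()), "Stool")
}

#' Subjects sampled at every required body site
#'
#' @param meta Sample metadata.
#' @param sites Required sites (default all ten).
#' @return Character vector of subject IDs.
#' @export
complete_subjects <- function(meta, sites = names(site_groups())) {
  got <- tapply(meta$body_site, meta$subject_id,
                function(s) all(sites %in% s))
  names(got)[got]
}

#' Per-clade prevalence across subjects
#'
#' Prevalence = fraction of subjects in which a clade is detected
#' (abundance above `floor`, default any retained read). Reported per body
#' site, for the upper digestive tract (detected in at least one of the
#' nine non-stool sites), and for stool. With
#' `complete_subjects_only = TRUE` (default) only subjects sampled at all
#' ten habitats enter the denominators, so scopes are comparable.
#'
#' @param ab A [clade_abundance()] table.
#' @param complete_subjects_only Restrict to fully sampled subjects.
#' @param floor Minimum abundance counted as detection (default 0, i.e.
#'   presence = abundance > 0).
#' @return `data.frame` with one row per clade: `lineage`, `name`, `rank`,
#'   one prevalence column per body site, plus `upper_tract` and `stool`.
#'   Attribute `n_subjects` records the denominator.
#' @export
prevalence_table <- function(ab, complete_subjects_only = TRUE, floor = 0) {
  stopifnot(inherits(ab, "clade_abundance"))
  meta <- ab$meta
  subs <- if (complete_subjects_only) complete_subjects(meta) else
    unique(meta$subject_id)
  if (!length(subs)) stop("no subjects satisfy the completeness criterion")
  keep <- meta$subject_id %in% subs
  present <- ab$ab[, keep, drop = FALSE] > floor
  meta <- meta[keep, , drop = FALSE]
  sites <- intersect(names(site_groups()), unique(meta$body_site))
  out <- data.frame(lineage = ab$taxonomy$lineage,
                    name = ab$taxonomy$name,
                    rank = ab$taxonomy$rank,
                    stringsAsFactors = FALSE)
  # subject-level presence: OR over a subject's samples within scope
  subj_presence <- function(cols) {
    f <- factor(meta$subject_id[cols], levels = subs)
    hit <- t(rowsum(t(present[, cols, drop = FALSE]) + 0, f) > 0)
    rowMeans(hit)
  }
  for (s in sites) out[[s]] <- subj_presence(meta$body_site == s)
  out$upper_tract <- subj_presence(meta$body_site %in% upper_tract_sites())
  out$stool <- if ("Stool" %in% meta$body_site)
    subj_presence(meta$body_site == "Stool") else 0
  attr(out, "n_subjects") <- length(subs)
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean; the
#' cross-sample variability statistic used to rank clades from most stable
#' to most variable.
#'
#' @param values Numeric vector with positive mean.
#' @return CV `>= 0`; `NA` (undefined) when the mean is not positive.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::sd(values) / m
}

#' Variability ranking of clades across all samples
#'
#' Pools samples from all body sites and ranks clades at one rank by their
#' coefficient of variation, lowest (most stable) first. Only clades
#' present above `min_abund` in at least `min_frac` of samples are
#' reported; clades with undefined CV (zero mean) are skipped.
#'
#' @param ab A [clade_abundance()] table.
#' @param rank Taxonomic rank (default genus).
#' @param min_abund Inclusion floor on relative abundance (default `1e-5`,
#'   i.e. > 0.001%).
#' @param min_frac Minimum fraction of samples above the floor (default
#'   0.5).
#' @return `data.frame` with `lineage`, `name`, `mean_abundance`, `cv`,
#'   sorted by ascending CV.
#' @export
variability_report <- function(ab, rank = "genus", min_abund = 1e-5,
                               min_frac = 0.5) {
  m <- at_rank(ab, rank)
  keep <- rowMeans(m > min_abund) >= min_frac
  m <- m[keep, , drop = FALSE]
  cv <- apply(m, 1L, coefficient_of_variation)
  res <- data.frame(lineage = rownames(m),
                    name = vapply(rownames(m), function(l)
                      parse_lineage(l)$name, character(1)),
                    mean_abundance = rowMeans(m),
                    cv = cv,
                    stringsAsFactors = FALSE)
  res <- res[!is.na(res$cv), , drop = FALSE]
  res <- res[order(res$cv, res$lineage), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genera shared between the oral cavity and stool within subjects
#'
#' A genus overlaps when, in the same subject, it is detected in at least
#' one upper-tract site and in stool. Returns the genera whose overlap
#' reaches `subject_threshold` of the fully sampled subjects.
#'
#' @param ab A [clade_abundance()] table.
#' @param subject_threshold Minimum fraction of subjects with same-subject
#'   oral and stool presence (default 0.45).
#' @param rank Taxonomic rank of the clades considered (default genus).
#' @param floor Detection floor, as in [prevalence_table()].
#' @return `data.frame` with `lineage`, `name`, `overlap_fraction`,
#'   sorted by descending overlap.
#' @export
oral_stool_overlap <- function(ab, subject_threshold = 0.45,
                               rank = "genus", floor = 0) {
  stopifnot(inherits(ab, "clade_abundance"))
  meta <- ab$meta
  subs <- complete_subjects(meta)
  if (!length(subs)) stop("no fully sampled subjects")
  idx <- which(ab$taxonomy$rank == rank)
  present <- ab$ab[idx, meta$subject_id %in% subs, drop = FALSE] > floor
  meta <- meta[meta$subject_id %in% subs, , drop = FALSE]
  f <- factor(meta$subject_id, levels = subs)
  in_scope <- function(sites) {
    cols <- meta$body_site %in% sites
    t(rowsum(t(present[, cols, drop = FALSE]) + 0, f[cols]) > 0)
  }
  oral <- in_scope(upper_tract_sites())
  stool <- in_scope("Stool")
  both <- rowMeans(oral & stool)
  res <- data.frame(lineage = rownames(present),
                    name = ab$taxonomy$name[idx],
                    overlap_fraction = both,
                    stringsAsFactors = FALSE)
  res <- res[res$overlap_fraction >= subject_threshold, , drop = FALSE]
  res <- res[order(-res$overlap_fraction, res$lineage), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Firmicutes:Bacteroidetes abundance ratio per body site or group
#'
#' The compositional statistic that motivates the four-group habitat
#' partition: the ratio of mean Firmicutes to mean Bacteroidetes relative
#' abundance per unit. A unit with zero mean Bacteroidetes gets an `Inf`
#' sentinel.
#'
#' @param ab A [clade_abundance()] table with phylum-level rows.
#' @param by `"body_site"` (default) or `"group"`.
#' @param map Site-to-group map used when `by = "group"`.
#' @return `data.frame` with `unit`, `firmicutes_mean`,
#'   `bacteroidetes_mean`, `ratio`, and (per site) the assigned `group`.
#' @export
fb_ratio <- function(ab, by = c("body_site", "group"), map = site_groups()) {
  by <- match.arg(by)
  ph <- at_rank(ab, "phylum")
  firm <- grep("\\|Firmicutes$", rownames(ph))
  bact <- grep("\\|Bacteroidetes$", rownames(ph))
  if (!length(firm) || !length(bact))
    stop("phylum-level Firmicutes/Bacteroidetes rows not found")
  unit <- if (by == "body_site") ab$meta$body_site else
    unname(map[ab$meta$body_site])
  fm <- tapply(colSums(ph[firm, , drop = FALSE]), unit, mean)
  bm <- tapply(colSums(ph[bact, , drop = FALSE]), unit, mean)
  res <- data.frame(unit = names(fm),
                    firmicutes_mean = as.numeric(fm),
                    bacteroidetes_mean = as.numeric(bm),
                    ratio = ifelse(bm == 0, Inf, as.numeric(fm) / as.numeric(bm)),
                    stringsAsFactors = FALSE)
  if (by == "body_site") res$group <- unname(map[res$unit])
  rownames(res) <- NULL
  res
}
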