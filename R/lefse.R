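#' Kruskal-Wallis screen for one feature
#'
#' Standard Kruskal-Wallis rank test with midrank tie correction and a
#' chi-square p-value on `k - 1` degrees of freedom. The first stage of the
#' biomarker pipeline: features whose abundance does not differ among the
#' sample classes at this stage are never considered further.
#'
#' @param values Per-sample abundance of one clade.
#' @param classes Class label per sample (at least two classes).
#' @return List with `H` (statistic) and `p`; all-identical values give
#'   `H = 0`, `p = 1`.
#' @export
kw_screen <- function(values, classes) {
  classes <- factor(classes)
  stopifnot(length(values) == length(classes), nlevels(classes) >= 2)
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, classes)
  list(H = unname(kt$statistic), p = kt$p.value)
}

# Wilcoxon rank-sum with normal approximation (midranks, continuity
# correction): abundance data are tie-rich, so the approximate test is used
# uniformly rather than switching to the exact distribution at small n.
rank_sum_p <- function(x, y) {
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  u <- unname(wt$statistic)                      # Mann-Whitney U of x
  list(p = wt$p.value, x_higher = u > length(x) * length(y) / 2)
}

#' Pairwise Wilcoxon biological-consistency check for one feature
#'
#' Candidate enriched class = the class with the highest mean abundance.
#' The feature is biologically consistent when every unpaired Wilcoxon
#' rank-sum comparison between the candidate class and each other class is
#' significant at `alpha` and agrees in direction (candidate higher). With
#' two classes this reduces to a single rank-sum test.
#'
#' @inheritParams kw_screen
#' @param alpha Per-comparison significance level.
#' @return List with `consistent` (flag), `enriched_class`, and `p_values`
#'   (named vector of the pairwise p-values).
#' @export
pairwise_wilcoxon_consistency <- function(values, classes, alpha = 0.05) {
  classes <- factor(classes)
  means <- tapply(values, classes, mean)
  cand <- names(means)[which.max(means)]   # ties: first level, deterministic
  others <- setdiff(levels(classes), cand)
  ps <- stats::setNames(numeric(length(others)), others)
  ok <- TRUE
  for (o in others) {
    r <- rank_sum_p(values[classes == cand], values[classes == o])
    ps[o] <- r$p
    if (is.na(r$p) || r$p >= alpha || !r$x_higher) ok <- FALSE
  }
  list(consistent = ok, enriched_class = cand, p_values = ps)
}

# Two-class Fisher linear discriminant direction with ridge regularization
# of the pooled within-class scatter (guards the singular case that is the
# rule, not the exception, for sparse clade features).
fisher_lda_direction <- function(X, cls) {
  lv <- levels(cls)
  m1 <- colMeans(X[cls == lv[1], , drop = FALSE])
  m2 <- colMeans(X[cls == lv[2], , drop = FALSE])
  cov_w <- function(Z) {
    if (nrow(Z) < 2) return(matrix(0, ncol(Z), ncol(Z)))
    stats::cov(Z) * (nrow(Z) - 1)
  }
  Sw <- (cov_w(X[cls == lv[1], , drop = FALSE]) +
           cov_w(X[cls == lv[2], , drop = FALSE])) / max(1, nrow(X) - 2)
  ridge <- 1e-6 * mean(diag(Sw)) + 1e-10
  w <- solve(Sw + diag(ridge, ncol(X)), m1 - m2)
  list(w = w, m1 = m1, m2 = m2)
}

#' Bootstrapped linear-discriminant effect sizes
#'
#' Ranks screened features by the effect size of their class difference.
#' Abundances (fractions in `[0, 1]`) are rescaled to parts-per-million,
#' then for each bootstrap round a per-class subsample is drawn and a
#' two-class Fisher linear discriminant is fitted over all features
#' jointly. Each feature's discrimination magnitude is the average of its
#' absolute raw class-mean difference and its share of the
#' discriminant-axis class separation (unit discriminant coefficient times
#' axis mean separation). Round averages are reported as
#' `log10(1 + magnitude)`, so the conventional pass threshold of 2
#' corresponds to a ~100 ppm class difference; abundant clades score 4-6.
#'
#' @param X Feature matrix, features in rows, samples in columns, values
#'   relative abundances in `[0, 1]`.
#' @param classes Two-level class label per sample (focal class vs rest).
#' @param n_boot Bootstrap rounds (default 30).
#' @param subsample_fraction Per-class subsample fraction per round
#'   (default 2/3).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Named numeric vector of log10 effect sizes, one per feature.
#' @export
lda_effect_size <- function(X, classes, n_boot = 30,
                            subsample_fraction = 2 / 3, seed = 1) {
  X <- as.matrix(X)
  cls <- factor(classes)
  stopifnot(nlevels(cls) == 2, ncol(X) == length(cls))
  Xs <- t(X) * 1e6                       # samples x features, ppm scale
  set.seed(seed)
  acc <- numeric(nrow(X))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(levels(cls), function(l) {
      pool <- which(cls == l)
      n <- max(2L, floor(subsample_fraction * length(pool)))
      sample(pool, min(n, length(pool)))
    }))
    Xi <- Xs[idx, , drop = FALSE]
    ci <- droplevels(cls[idx])
    if (nlevels(ci) < 2) next
    fit <- fisher_lda_direction(Xi, ci)
    w_norm <- sqrt(sum(fit$w^2))
    if (w_norm == 0) { coeff <- rep(0, ncol(Xi)) } else {
      w_unit <- fit$w / w_norm
      axis_sep <- abs(sum(w_unit * (fit$m1 - fit$m2)))
      coeff <- abs(w_unit) * axis_sep
    }
    acc <- acc + 0.5 * (abs(fit$m1 - fit$m2) + coeff)
  }
  res <- acc / n_boot
  stats::setNames(log10(1 + res), rownames(X))
}

#' Biomarker discovery across all taxonomic ranks
#'
#' The full effect-size pipeline on a classed abundance table: (1)
#' Kruskal-Wallis significance screen per feature, (2) pairwise Wilcoxon
#' biological-consistency check, (3) bootstrapped linear-discriminant
#' effect-size ranking of the survivors (enriched class versus the pooled
#' complement). All clades at all ranks are treated as features, so a
#' biomarker can surface at any level from phylum to genus.
#'
#' Two class-comparison strategies are provided. `"all_against_all"`
#' screens with the multi-class Kruskal-Wallis test. `"one_against_rest"`
#' (slightly more stringent for the focal class) pools the complement
#' classes into one for the significance stage, while consistency is still
#' required against each remaining class individually.
#'
#' @param ab A [clade_abundance()] table.
#' @param classes Named class labels covering the samples (e.g.
#'   [sample_groups()] output), at least two classes with at least three
#'   samples each.
#' @param strategy `"all_against_all"` (default) or `"one_against_rest"`.
#' @param alpha Significance level for both testing stages (default 0.05).
#' @param lda_threshold Log10 effect-size pass threshold (default 2).
#' @param n_boot,subsample_fraction Bootstrap settings, see
#'   [lda_effect_size()].
#' @param seed Integer seed for the bootstrap.
#' @param all Return every feature (with its `passed` flag) instead of
#'   passed biomarkers only.
#' @return `data.frame` with columns `feature`, `rank`, `kw_p`,
#'   `consistent`, `enriched_class`, `effect_size`, `passed`, sorted by
#'   effect size (descending, feature name breaking ties).
#' @export
run_lefse <- function(ab, classes,
                      strategy = c("all_against_all", "one_against_rest"),
                      alpha = 0.05, lda_threshold = 2.0,
                      n_boot = 30, subsample_fraction = 2 / 3,
                      seed = 1, all = FALSE) {
  stopifnot(inherits(ab, "clade_abundance"))
  strategy <- match.arg(strategy)
  cls <- factor(classes[colnames(ab$ab)])
  if (anyNA(cls)) stop("samples without class labels")
  if (nlevels(cls) < 2) stop("need at least two classes")
  small <- table(cls) < 3
  if (any(small))
    stop("classes with fewer than 3 samples: ",
         paste(names(which(small)), collapse = ", "),
         " - merge or drop them before running biomarker discovery")

  feats <- rownames(ab$ab)
  n <- length(feats)
  kw_p <- rep(NA_real_, n)
  consistent <- rep(FALSE, n)
  enriched <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    v <- ab$ab[i, ]
    means <- tapply(v, cls, mean)
    cand <- names(means)[which.max(means)]
    scr_cls <- if (strategy == "one_against_rest") {
      factor(ifelse(cls == cand, cand, "rest"))
    } else cls
    kw <- kw_screen(v, scr_cls)
    kw_p[i] <- kw$p
    if (is.na(kw$p) || kw$p >= alpha) next
    cons <- pairwise_wilcoxon_consistency(v, cls, alpha)
    consistent[i] <- cons$consistent
    enriched[i] <- cons$enriched_class
  }

  effect <- rep(NA_real_, n)
  survivors <- which(!is.na(kw_p) & kw_p < alpha & consistent)
  for (cl in unique(enriched[survivors])) {
    rows <- survivors[enriched[survivors] == cl]
    bin <- factor(ifelse(cls == cl, cl, "rest"), levels = c(cl, "rest"))
    effect[rows] <- lda_effect_size(
      ab$ab[rows, , drop = FALSE], bin,
      n_boot = n_boot, subsample_fraction = subsample_fraction, seed = seed)
  }

  res <- data.frame(
    feature = feats,
    rank = ab$taxonomy$rank,
    kw_p = kw_p,
    consistent = consistent,
    enriched_class = enriched,
    effect_size = effect,
    stringsAsFactors = FALSE
  )
  res$passed <- !is.na(res$kw_p) & res$kw_p < alpha & res$consistent &
    !is.na(res$effect_size) & res$effect_size >= lda_threshold
  ord <- order(-ifelse(is.na(res$effect_size), -Inf, res$effect_size),
               res$feature)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  if (!all) res <- res[res$passed, , drop = FALSE]
  res
}
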