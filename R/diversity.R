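#' Default body-site to community-group assignment
#'
#' The ten digestive tract habitats partition into four community types by
#' their Firmicutes:Bacteroidetes balance: G1 = buccal mucosa (BM),
#' keratinized gingiva (KG), hard palate (HP); G2 = saliva (Sal), tongue
#' dorsum (TD), palatine tonsils (PT), throat (Th); G3 = supra- and
#' sub-gingival plaque (SupP, SubP); G4 = stool.
#'
#' @return Named character vector mapping body-site code to group label.
#' @export
site_groups <- function() {
  c(BM = "G1", KG = "G1", HP = "G1",
    Sal = "G2", TD = "G2", PT = "G2", Th = "G2",
    SupP = "G3", SubP = "G3",
    Stool = "G4")
}

#' Map samples to community groups via their body site
#'
#' @param meta Sample metadata with `sample_id` and `body_site`.
#' @param map Site-to-group map, default [site_groups()].
#' @return Named character vector of group labels, names = sample IDs.
#' @export
sample_groups <- function(meta, map = site_groups()) {
  unmapped <- setdiff(unique(meta$body_site), names(map))
  if (length(unmapped))
    stop("body sites without group assignment: ",
         paste(unmapped, collapse = ", "))
  stats::setNames(unname(map[meta$body_site]), meta$sample_id)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC(p, q) = sum(|p - q|) / sum(p + q)`, in `[0, 1]`; 0 for identical
#' profiles, 1 for disjoint supports. A semimetric: the triangle inequality
#' is not guaranteed.
#'
#' @param p,q Non-negative abundance vectors on the same clade index.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  tot <- sum(p) + sum(q)
  if (tot == 0) stop("Bray-Curtis undefined: both vectors are all zero")
  sum(abs(p - q)) / tot
}

#' Pairwise Bray-Curtis dissimilarity matrix at one rank
#'
#' @param ab A [clade_abundance()] table.
#' @param rank Taxonomic rank of the profiles (default genus, the finest
#'   reliably classified level).
#' @return Symmetric dissimilarity matrix with sample IDs as dimnames.
#' @export
bray_curtis_matrix <- function(ab, rank = "genus") {
  m <- t(at_rank(ab, rank))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Inverse Simpson diversity of an abundance vector
#'
#' `D = 1 / sum(p^2)`: the effective number of equally abundant taxa, an
#' evenness-sensitive alpha diversity. Equals the support size for a
#' uniform profile and 1 for a single-taxon community.
#'
#' @param p Relative abundance vector (sums to ~1).
#' @return Diversity value `>= 1`.
#' @export
inverse_simpson <- function(p) {
  stopifnot(all(p >= 0))
  if (sum(p) == 0) stop("inverse Simpson undefined for an all-zero vector")
  1 / sum(p^2)
}

#' Per-sample inverse Simpson diversity at one rank
#'
#' @inheritParams bray_curtis_matrix
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(ab, rank = "genus") {
  vegan::diversity(t(at_rank(ab, rank)), index = "invsimpson")
}

#' Within/between-group community similarity summary
#'
#' Summarizes a pairwise Bray-Curtis matrix as the mean and standard
#' deviation of similarity (`1 - dissimilarity`) over all within-group
#' sample pairs (diagonal cells, self-pairs excluded) and all cross-group
#' pairs (off-diagonal cells). Higher diagonal than off-diagonal values
#' indicate that groups form distinct community structures.
#'
#' @param D Symmetric dissimilarity matrix (as from
#'   [bray_curtis_matrix()]).
#' @param groups Named group label vector covering `rownames(D)`.
#' @param as Report cells as `"similarity"` (default) or
#'   `"dissimilarity"`.
#' @return Object of class `group_structure` with matrices `mean`, `sd`
#'   and `n` (pair counts); groups with fewer than two samples get `NA`
#'   diagonal cells.
#' @export
group_structure_summary <- function(D, groups, as = c("similarity", "dissimilarity")) {
  as <- match.arg(as)
  ids <- rownames(D)
  g <- groups[ids]
  if (anyNA(g)) stop("samples without group labels")
  labs <- sort(unique(g))
  k <- length(labs)
  mean_m <- sd_m <- n_m <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  vals <- if (as == "similarity") 1 - D else D
  for (i in seq_len(k)) {
    for (j in i:k) {
      vi <- which(g == labs[i]); vj <- which(g == labs[j])
      if (i == j) {
        if (length(vi) < 2) next
        block <- vals[vi, vi, drop = FALSE]
        pool <- block[upper.tri(block)]
      } else {
        pool <- as.vector(vals[vi, vj, drop = FALSE])
      }
      mean_m[i, j] <- mean_m[j, i] <- mean(pool)
      sd_m[i, j] <- sd_m[j, i] <- stats::sd(pool)
      n_m[i, j] <- n_m[j, i] <- length(pool)
    }
  }
  structure(list(mean = mean_m, sd = sd_m, n = n_m, as = as),
            class = "group_structure")
}

#' @export
print.group_structure <- function(x, digits = 2, ...) {
  cat(sprintf("<group_structure> mean %s (sd):\n", x$as))
  k <- nrow(x$mean)
  out <- matrix("", k, k, dimnames = dimnames(x$mean))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- sprintf("%.*f ± %.*f", digits, x$mean[i, j],
                         digits, x$sd[i, j])
  print(out, quote = FALSE)
  invisible(x)
}

#' Test within- versus between-group pairwise distances for one group
#'
#' Pools the within-group pairwise dissimilarities of the focal group and
#' its dissimilarities to all other groups' samples, then compares the two
#' pools. The default Welch t-test mirrors the usual reporting convention;
#' a permutation alternative is provided because pairwise distances from
#' shared samples are not independent observations.
#'
#' @inheritParams group_structure_summary
#' @param group Focal group label.
#' @param method `"t"` (Welch, default) or `"permutation"` (group labels
#'   permuted across samples, mean within-between difference as statistic).
#' @param n_perm Permutations when `method = "permutation"`.
#' @return Two-sided p-value.
#' @export
within_between_test <- function(D, groups, group,
                                method = c("t", "permutation"),
                                n_perm = 999) {
  method <- match.arg(method)
  ids <- rownames(D)
  g <- groups[ids]
  pools <- wb_pools(D, g, group)
  if (length(pools$within) < 2 || length(pools$between) < 2)
    stop("degenerate within/between pools for group ", group)
  if (method == "t") {
    return(stats::t.test(pools$within, pools$between)$p.value)
  }
  obs <- mean(pools$within) - mean(pools$between)
  perm <- replicate(n_perm, {
    gp <- sample(g)
    p <- wb_pools(D, gp, group)
    mean(p$within) - mean(p$between)
  })
  (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
}

wb_pools <- function(D, g, group) {
  vi <- which(g == group)
  vo <- which(g != group)
  block <- D[vi, vi, drop = FALSE]
  list(within = block[upper.tri(block)],
       between = as.vector(D[vi, vo, drop = FALSE]))
}

#' Classical (metric) multidimensional scaling of a dissimilarity matrix
#'
#' Torgerson scaling: eigendecomposition of the double-centered squared
#' dissimilarity matrix, keeping the top `k` positive-eigenvalue axes.
#' Pairwise Euclidean distances of the embedding approximate the input
#' (exactly when the input is Euclidean and `k` spans all positive
#' eigenvalues).
#'
#' @param D Symmetric dissimilarity matrix.
#' @param k Number of embedding dimensions.
#' @return Numeric matrix of sample coordinates (`k` columns, fewer with a
#'   warning if the matrix has fewer positive eigenvalues).
#' @export
classical_mds <- function(D, k = 2) {
  stopifnot(k >= 1)
  D <- as.matrix(D)
  fit <- suppressWarnings(
    stats::cmdscale(D, k = min(k, nrow(D) - 1L), eig = TRUE))
  pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (k > pos) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes", pos, pos))
    fit$points <- fit$points[, seq_len(min(pos, ncol(fit$points))), drop = FALSE]
  }
  fit$points
}

#' Compare alpha diversity between two groups
#'
#' Welch two-sample t-test on per-sample diversity values (for example
#' inverse Simpson) between two community groups.
#'
#' @param alphas Named per-sample diversity vector.
#' @param groups Named group label vector covering the samples.
#' @param g1,g2 Group labels to contrast; `g1 == g2` returns 1 by
#'   convention.
#' @return Two-sided p-value. Zero variance in both groups yields 1 when
#'   the means are equal and 0 otherwise.
#' @export
alpha_group_contrast <- function(alphas, groups, g1, g2) {
  if (identical(g1, g2)) return(1)
  x <- alphas[names(groups)[groups == g1]]
  y <- alphas[names(groups)[groups == g2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two samples per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y)$p.value
}
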