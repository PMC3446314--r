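# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately re-derive each quantity from its textbook
# definition and stay independent of the implementation paths they check.

oracle_bray_curtis <- function(p, q) {
  num <- 0; den <- 0
  for (i in seq_along(p)) {
    num <- num + abs(p[i] - q[i])
    den <- den + p[i] + q[i]
  }
  num / den
}

oracle_inverse_simpson <- function(p) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[i]^2
  1 / s
}

oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  sqrt(v) / m
}

# Kruskal-Wallis H with midrank tie correction and chi-square p-value
oracle_kw <- function(values, classes) {
  r <- rank(values)
  N <- length(values)
  cls <- split(r, classes)
  H <- 12 / (N * (N + 1)) * sum(vapply(cls, function(ri)
    sum(ri)^2 / length(ri), numeric(1))) - 3 * (N + 1)
  ties <- table(values)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(H = H, p = stats::pchisq(H, length(cls) - 1, lower.tail = FALSE))
}

# Wilcoxon rank-sum two-sided p, normal approximation with midrank tie
# correction and continuity correction (the approximation the package
# applies uniformly)
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  z <- U - mu
  z <- z - sign(z) * 0.5
  min(1, 2 * stats::pnorm(-abs(z / sigma)))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Torgerson scaling by explicit double centering + eigendecomposition;
# returns the k-dim Gram matrix (rotation/sign free object for comparison)
oracle_mds_gram <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- seq_len(k)
  lam <- pmax(e$values[keep], 0)
  X <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), k)
  tcrossprod(X)
}

# naive O(n^2) descendant enumeration for count propagation
oracle_propagate <- function(counts) {
  lineages <- rownames(counts)
  ranks <- tractome::tract_ranks()
  parts <- lapply(strsplit(lineages, "|", fixed = TRUE), function(p) {
    p <- c(p, rep("unclassified", length(ranks) - length(p)))
    p
  })
  keys <- unique(unlist(lapply(parts, function(p)
    vapply(seq_along(ranks), function(d) paste(p[1:d], collapse = "|"),
           character(1)))))
  out <- matrix(0, length(keys), ncol(counts),
                dimnames = list(keys, colnames(counts)))
  for (k in keys) {
    pref <- strsplit(k, "|", fixed = TRUE)[[1]]
    for (i in seq_along(parts)) {
      if (identical(parts[[i]][seq_along(pref)], pref))
        out[k, ] <- out[k, ] + counts[i, ]
    }
  }
  out
}
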