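test_that("Bray-Curtis matches its definition and boundary cases", {
  p <- c(0.7, 0.3, 0)
  q <- c(0.2, 0.3, 0.5)
  expect_equal(bray_curtis(p, q), 0.5)
  expect_equal(bray_curtis(p, p), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all zero")
})

test_that("Bray-Curtis is symmetric and bounded on random compositions", {
  set.seed(14)
  for (i in 1:20) {
    p <- prop.table(rgamma(8, 1))
    q <- prop.table(rgamma(8, 1))
    d <- bray_curtis(p, q)
    expect_equal(d, bray_curtis(q, p))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, oracle_bray_curtis(p, q))
  }
})

test_that("pairwise dissimilarity matrix agrees with a direct double loop", {
  set.seed(8)
  coh <- generate_cohort(cohort_config(n_subjects = 3, seed = 77,
                                       defective_rate = 0,
                                       repeat_visit_rate = 0))
  ab <- qc_pipeline(coh$counts)$abundance
  D <- bray_curtis_matrix(ab)
  m <- at_rank(ab, "genus")
  for (i in 1:5) {
    a <- sample(colnames(m), 1); b <- sample(colnames(m), 1)
    want <- if (a == b) 0 else unname(oracle_bray_curtis(m[, a], m[, b]))
    expect_equal(D[a, b], want, tolerance = 1e-12)
  }
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("inverse Simpson equals its closed form and is maximized by evenness", {
  expect_equal(inverse_simpson(rep(0.2, 5)), 5)
  expect_equal(inverse_simpson(c(1, 0, 0)), 1)
  expect_equal(inverse_simpson(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_error(inverse_simpson(c(0, 0)), "all-zero")
  set.seed(2)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    p <- prop.table(rgamma(k, 1))
    expect_equal(inverse_simpson(p), oracle_inverse_simpson(p))
    expect_lte(inverse_simpson(p), k + 1e-12)  # uniform is the maximum
  }
})

test_that("within-group similarity is 1 for identical samples and the summary is symmetric", {
  m <- cbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0.5, 0),
             s3 = c(0, 0.1, 0.9), s4 = c(0.05, 0.15, 0.8))
  rownames(m) <- sprintf("Bacteria|P%d|c|o|f|g%d", 1:3, 1:3)
  meta <- make_meta(colnames(m), sites = c("BM", "BM", "Stool", "Stool"))
  ab <- abundance_fixture(m, meta)
  D <- bray_curtis_matrix(ab)
  gs <- group_structure_summary(D, sample_groups(meta))
  expect_equal(gs$mean["G1", "G1"], 1)
  expect_equal(gs$mean, t(gs$mean))
  expect_true(all(gs$mean >= 0 & gs$mean <= 1))
  # dissimilarity representation is the complement
  gd <- group_structure_summary(D, sample_groups(meta), as = "dissimilarity")
  expect_equal(gd$mean, 1 - gs$mean)
})

test_that("a group with fewer than two samples gets a flagged diagonal cell", {
  m <- cbind(s1 = c(0.5, 0.5), s2 = c(0.2, 0.8), s3 = c(0.9, 0.1))
  rownames(m) <- sprintf("Bacteria|P%d|c|o|f|g%d", 1:2, 1:2)
  meta <- make_meta(colnames(m), sites = c("BM", "BM", "Stool"))
  gs <- group_structure_summary(bray_curtis_matrix(abundance_fixture(m, meta)),
                                sample_groups(meta))
  expect_true(is.na(gs$mean["G4", "G4"]))
  expect_false(is.na(gs$mean["G1", "G4"]))
})

test_that("within- vs between-group tests behave at both extremes", {
  set.seed(31)
  coh <- generate_cohort(cohort_config(n_subjects = 8, seed = 55,
                                       defective_rate = 0,
                                       repeat_visit_rate = 0))
  ab <- qc_pipeline(coh$counts)$abundance
  D <- bray_curtis_matrix(ab)
  g <- sample_groups(ab$meta)
  for (gr in c("G1", "G4")) {
    expect_lt(within_between_test(D, g, gr), 1e-6)
    expect_lt(within_between_test(D, g, gr, method = "permutation",
                                  n_perm = 199), 0.02)
  }
})

test_that("label shuffles yield null-calibrated within-between p-values", {
  set.seed(99)
  coh <- generate_cohort(cohort_config(n_subjects = 4, seed = 12,
                                       defective_rate = 0,
                                       repeat_visit_rate = 0))
  ab <- qc_pipeline(coh$counts)$abundance
  D <- bray_curtis_matrix(ab)
  g <- sample_groups(ab$meta)
  over05 <- 0
  for (i in 1:100) {
    gp <- setNames(sample(g), names(g))
    p <- within_between_test(D, gp, "G2", method = "permutation",
                             n_perm = 99)
    if (p > 0.05) over05 <- over05 + 1
  }
  expect_gte(over05, 90)
})

test_that("classical MDS reproduces Euclidean configurations", {
  # 3 collinear points, distances (1, 1, 2): exactly 1-D Euclidean
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  X <- classical_mds(D, k = 1)
  expect_equal(as.vector(dist(X)), c(1, 2, 1), tolerance = 1e-9)
  # random 2-D configuration recovered up to rigid motion
  set.seed(6)
  P <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(P))
  X2 <- classical_mds(D2, k = 2)
  expect_equal(as.matrix(dist(X2)), D2, tolerance = 1e-6, ignore_attr = TRUE)
  # duplicated samples embed at identical coordinates
  D3 <- as.matrix(dist(P[c(1, 1, 2:10), ]))
  X3 <- classical_mds(D3, k = 2)
  expect_equal(X3[1, ], X3[2, ], tolerance = 1e-9, ignore_attr = TRUE)
  # k beyond the positive-eigenvalue count is truncated with a warning
  expect_warning(Xt <- classical_mds(D2, k = 5), "positive eigenvalues")
  expect_lte(ncol(Xt), 2)
})

test_that("alpha-diversity group contrasts have power and honour conventions", {
  set.seed(88)
  g <- setNames(rep(c("A", "B"), each = 50), paste0("s", 1:100))
  shifted <- setNames(c(rnorm(50), rnorm(50, 3)), names(g))
  expect_lt(alpha_group_contrast(shifted, g, "A", "B"), 1e-6)
  expect_equal(alpha_group_contrast(shifted, g, "A", "A"), 1)
  flat <- setNames(rep(2, 100), names(g))
  expect_equal(alpha_group_contrast(flat, g, "A", "B"), 1)
})

test_that("the alpha contrast is calibrated under the null", {
  set.seed(4)
  g <- setNames(rep(c("A", "B"), each = 20), paste0("s", 1:40))
  rej <- mean(replicate(1000, {
    x <- setNames(rnorm(40), names(g))
    alpha_group_contrast(x, g, "A", "B") < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
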