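test_that("the Kruskal-Wallis screen matches the hand formula", {
  r <- kw_screen(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$H, 3.857, tolerance = 5e-4)
  # all-identical values are a degenerate non-signal
  expect_equal(kw_screen(rep(1, 9), rep(c("a", "b", "c"), 3))$p, 1)
})

test_that("pairwise Wilcoxon consistency accepts ordered supports and rejects overlap", {
  # strictly ordered, non-overlapping supports across three classes
  v <- c(1:10, 21:30, 41:50)
  cls <- rep(c("lo", "mid", "hi"), each = 10)
  r <- pairwise_wilcoxon_consistency(v, cls)
  expect_true(r$consistent)
  expect_equal(r$enriched_class, "hi")

  # high vs one class but indistinguishable from the third -> inconsistent
  set.seed(10)
  twin <- rnorm(10, 5)
  v2 <- c(rnorm(10, 0), twin, twin)
  r2 <- pairwise_wilcoxon_consistency(v2, cls)
  expect_false(r2$consistent)

  # two identical classes -> inconsistent
  v3 <- rep(c(1, 2, 3, 4, 5), 2)
  r3 <- pairwise_wilcoxon_consistency(v3, rep(c("a", "b"), each = 5))
  expect_false(r3$consistent)
  expect_gt(min(r3$p_values), 0.9)
})

test_that("LDA effect sizes separate planted from null features", {
  set.seed(77)
  n <- 30
  cls <- rep(c("case", "rest"), each = n)
  planted <- c(rnorm(n, 0.10, 0.02), rnorm(n, 0.001, 0.0005))
  planted <- pmax(planted, 0)
  X <- rbind(planted = planted)
  es <- lda_effect_size(X, cls, seed = 5)
  expect_gte(es["planted"], 2)
  # raw log10 mean difference lower-bounds the reported score
  gm <- abs(mean(planted[1:n]) - mean(planted[-(1:n)])) * 1e6
  expect_gte(es["planted"], log10(1 + 0.5 * gm) - 0.3)
  # features whose class distributions are identical show no separation
  Xnull <- rbind(n1 = rep(0.01, 2 * n) + rnorm(2 * n, 0, 1e-4),
                 n2 = rep(0.005, 2 * n) + rnorm(2 * n, 0, 2e-4))
  es_null <- lda_effect_size(pmax(Xnull, 0), cls, seed = 5)
  expect_true(all(es_null < 2))
})

test_that("effect sizes are deterministic given the seed and invariant to sample renaming", {
  set.seed(3)
  X <- matrix(runif(5 * 40, 0, 0.05), 5, 40,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:40)))
  cls <- rep(c("a", "b"), each = 20)
  e1 <- lda_effect_size(X, cls, seed = 9)
  e2 <- lda_effect_size(X, cls, seed = 9)
  expect_identical(e1, e2)
  X2 <- X
  colnames(X2) <- paste0("renamed", 1:40)
  expect_equal(unname(lda_effect_size(X2, cls, seed = 9)), unname(e1))
  expect_false(identical(e1, lda_effect_size(X, cls, seed = 10)))
})

test_that("run_lefse refuses degenerate class structures", {
  set.seed(1)
  coh <- generate_cohort(cohort_config(n_subjects = 4, seed = 2,
                                       defective_rate = 0,
                                       repeat_visit_rate = 0))
  ab <- qc_pipeline(coh$counts)$abundance
  one <- setNames(rep("only", ncol(ab$ab)), colnames(ab$ab))
  expect_error(run_lefse(ab, one), "at least two classes")
  tiny <- setNames(rep("big", ncol(ab$ab)), colnames(ab$ab))
  tiny[1:2] <- "tiny"
  expect_error(run_lefse(ab, tiny), "fewer than 3")
})

test_that("planted biomarkers are recovered and the record list is deterministic", {
  coh <- generate_cohort(harness_config(seed = 101, n_subjects = 15))
  qc <- qc_pipeline(coh$counts)
  g <- sample_groups(qc$abundance$meta)
  res <- run_lefse(qc$abundance, g, seed = 7, all = TRUE)
  planted <- coh$truth$planted$lineage
  hit <- res[res$feature %in% planted, ]
  expect_equal(nrow(hit), 5)
  expect_true(all(hit$passed))
  expect_equal(sort(unname(
    setNames(hit$enriched_class, hit$feature)[coh$truth$planted$lineage])),
    sort(coh$truth$planted$group))
  res2 <- run_lefse(qc$abundance, g, seed = 7, all = TRUE)
  expect_identical(res, res2)
  # default output returns passed biomarkers only, sorted by effect size
  top <- run_lefse(qc$abundance, g, seed = 7)
  expect_true(all(top$passed))
  expect_false(is.unsorted(rev(top$effect_size)))
})

test_that("one-against-rest strategy also recovers planted biomarkers", {
  coh <- generate_cohort(harness_config(seed = 202, n_subjects = 15))
  qc <- qc_pipeline(coh$counts)
  res <- run_lefse(qc$abundance, sample_groups(qc$abundance$meta),
                   strategy = "one_against_rest", seed = 7)
  expect_true(all(coh$truth$planted$lineage %in% res$feature))
})

test_that("effect size is monotone in the planted fold change", {
  prev <- -Inf
  for (fold in c(2, 5, 10, 50)) {
    cfg <- cohort_config(n_subjects = 12, composition = "shared",
                         n_null_genera = 20, rare_phyla = NULL,
                         defective_rate = 0, repeat_visit_rate = 0,
                         planted = data.frame(name = "SimGenus001",
                                              group = "G4", fold = fold),
                         seed = 400)
    coh <- generate_cohort(cfg)
    qc <- qc_pipeline(coh$counts)
    res <- run_lefse(qc$abundance, sample_groups(qc$abundance$meta),
                     seed = 11, all = TRUE)
    es <- res$effect_size[res$feature == coh$truth$planted$lineage]
    es <- ifelse(is.na(es), 0, es)
    expect_gte(es, prev)
    prev <- es
  }
})

test_that("a clade and its only-child parent receive identical test results", {
  coh <- generate_cohort(cohort_config(n_subjects = 10, seed = 31,
                                       defective_rate = 0,
                                       repeat_visit_rate = 0,
                                       rare_phyla = NULL))
  qc <- qc_pipeline(coh$counts)
  # the TM7 lineage is a single chain: phylum -> genus share one vector
  tm7 <- grep("^Bacteria\\|TM7", rownames(qc$abundance$ab), value = TRUE)
  expect_gte(length(tm7), 2)
  for (i in seq_along(tm7)[-1]) {
    expect_equal(qc$abundance$ab[tm7[1], ], qc$abundance$ab[tm7[i], ])
  }
  res <- run_lefse(qc$abundance, sample_groups(qc$abundance$meta),
                   seed = 5, all = TRUE)
  rows <- res[res$feature %in% tm7, ]
  expect_equal(length(unique(rows$kw_p)), 1)
  expect_equal(length(unique(rows$consistent)), 1)
})
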