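# a hand-built cohort of 4 complete subjects over all ten sites:
# gA present everywhere; gB present in exactly half the subjects' stool and
# nowhere else; gC oral-only; gD present orally and in stool for 3/4 subjects
prevalence_fixture <- function() {
  sites <- names(site_groups())
  subs <- paste0("P", 1:4)
  meta <- expand.grid(subject_id = subs, body_site = sites,
                      stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$subject_id, meta$body_site, sep = "_")
  meta$visit <- 1L
  lin <- sprintf("Bacteria|Ph%d|c|o|f|g%s", 1:4, LETTERS[1:4])
  m <- matrix(0, 4, nrow(meta), dimnames = list(lin, meta$sample_id))
  m[1, ] <- 0.4                                    # gA ubiquitous
  m[2, meta$body_site == "Stool" &
        meta$subject_id %in% c("P1", "P2")] <- 0.3  # gB stool, half subjects
  m[3, meta$body_site != "Stool"] <- 0.2           # gC oral-only
  m[4, meta$body_site %in% c("Sal", "Stool") &
        meta$subject_id != "P4"] <- 0.1             # gD shared, 3/4 subjects
  counts <- m * 1000
  ab <- normalize_abundance(propagate_counts(
    clade_counts(counts, meta[, c("sample_id", "subject_id",
                                  "body_site", "visit")])))
  ab
}

test_that("prevalence is computed per site, upper tract and stool", {
  ab <- prevalence_fixture()
  pv <- prevalence_table(ab)
  expect_equal(attr(pv, "n_subjects"), 4)
  gA <- pv[pv$name == "gA", ]
  expect_equal(gA$upper_tract, 1)
  expect_equal(gA$stool, 1)
  expect_equal(gA$Sal, 1)
  gB <- pv[pv$name == "gB", ]
  expect_equal(gB$stool, 0.5)
  expect_equal(gB$upper_tract, 0)
  gC <- pv[pv$name == "gC", ]
  expect_equal(gC$stool, 0)
  expect_equal(gC$upper_tract, 1)
})

test_that("prevalence is monotone under scope widening", {
  ab <- prevalence_fixture()
  pv <- prevalence_table(ab)
  for (s in upper_tract_sites()) {
    expect_true(all(pv$upper_tract >= pv[[s]] - 1e-12))
  }
})

test_that("rare-phylum prevalence matches the generator's presence probability", {
  coh <- generate_cohort(cohort_config(
    n_subjects = 150, defective_rate = 0, repeat_visit_rate = 0,
    rare_phyla = data.frame(name = "SR1", presence_prob = 0.8,
                            ab_min = 0.001, ab_max = 0.01),
    seed = 61))
  ab <- qc_pipeline(coh$counts)$abundance
  pv <- prevalence_table(ab)
  sr1 <- pv[grepl("^Bacteria\\|SR1$", pv$lineage), ]
  expect_equal(sr1$upper_tract, 0.8, tolerance = 0.07 / 0.8)
  # and it matches the per-subject truth draws exactly up to sampling misses
  planted_frac <- mean(coh$truth$rare_presence[, "SR1"])
  expect_lte(abs(sr1$upper_tract - planted_frac), 0.02)
})

test_that("the coefficient of variation matches its formula and is scale invariant", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3)
  expect_equal(coefficient_of_variation(c(2, 4)), oracle_cv(c(2, 4)))
  expect_true(is.na(coefficient_of_variation(c(0, 0))))
  set.seed(17)
  for (i in 1:10) {
    x <- rgamma(20, 2)
    k <- runif(1, 0.1, 50)
    expect_equal(coefficient_of_variation(k * x),
                 coefficient_of_variation(x))
    expect_equal(coefficient_of_variation(x), oracle_cv(x))
  }
})

test_that("variability ranking follows the generator's dispersion structure", {
  # high theta -> low dispersion; mix two cohorts' samples is overkill, so
  # instead verify the report's filter and ordering on a constructed table
  sites <- rep("TD", 6)
  meta <- make_meta(paste0("s", 1:6), subjects = paste0("P", 1:6),
                    sites = sites)
  m <- rbind(stable = c(0.30, 0.31, 0.29, 0.30, 0.31, 0.29),
             wild = c(0.60, 0.05, 0.60, 0.05, 0.60, 0.05),
             rarely = c(1e-7, 0, 0, 1e-7, 0, 0))
  m <- rbind(m, filler = 1 - colSums(m))
  rownames(m) <- sprintf("Bacteria|P%d|c|o|f|%s", 1:4, rownames(m))
  ab <- abundance_fixture(m, meta)
  vr <- variability_report(ab)
  expect_false(any(grepl("rarely", vr$lineage)))  # below inclusion rule
  expect_lt(which(grepl("stable", vr$lineage)),
            which(grepl("wild", vr$lineage)))
})

test_that("oral-stool overlap returns exactly the genera shared within subjects", {
  ab <- prevalence_fixture()
  ov <- oral_stool_overlap(ab, subject_threshold = 0.45)
  expect_true(any(ov$name == "gA"))   # everywhere -> overlap 1
  expect_true(any(ov$name == "gD"))   # shared in 3/4 = 0.75
  expect_false(any(ov$name == "gC"))  # oral only
  expect_false(any(ov$name == "gB"))  # stool only
  # the overlap list shrinks as the threshold rises
  ov90 <- oral_stool_overlap(ab, subject_threshold = 0.9)
  expect_true(all(ov90$lineage %in% ov$lineage))
  expect_false(any(ov90$name == "gD"))
})

test_that("Firmicutes:Bacteroidetes ratios follow phylum means", {
  meta <- make_meta(paste0("s", 1:4), sites = c("BM", "BM", "Stool", "Stool"))
  m <- rbind(
    "Bacteria|Firmicutes|Bacilli|Lactobacillales|Streptococcaceae|Streptococcus" =
      c(0.6, 0.6, 0.2, 0.2),
    "Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Bacteroidaceae|Bacteroides" =
      c(0.2, 0.2, 0.7, 0.7),
    "Bacteria|Proteobacteria|Gamma|Pseudomonadales|Moraxellaceae|Moraxella" =
      c(0.2, 0.2, 0.1, 0.1))
  ab <- abundance_fixture(m, meta)
  fb <- fb_ratio(ab)
  expect_equal(fb$ratio[fb$unit == "BM"], 3)
  expect_lt(fb$ratio[fb$unit == "Stool"], 1)
  expect_gt(fb$bacteroidetes_mean[fb$unit == "Stool"], 0.6)
  # an all-Firmicutes community yields the infinity sentinel
  m2 <- m[1, , drop = FALSE] * 0 + 1
  rownames(m2) <- rownames(m)[1]
  ab2 <- abundance_fixture(rbind(m2, "Bacteria|Bacteroidetes" = 0), meta)
  expect_true(is.infinite(fb_ratio(ab2)$ratio[1]))
})

test_that("the default synthetic stool community is Bacteroidetes-dominant", {
  coh <- generate_cohort(cohort_config(n_subjects = 100, sites = "Stool",
                                       defective_rate = 0,
                                       repeat_visit_rate = 0, seed = 10))
  ab <- qc_pipeline(coh$counts)$abundance
  bact <- at_rank(ab, "phylum")["Bacteria|Bacteroidetes", ]
  expect_gt(mean(bact), 0.6)
})
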