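# Small programmatic fixtures shared across test files.

make_meta <- function(sample_ids, subjects = sample_ids,
                      sites = rep("TD", length(sample_ids)),
                      visits = rep(1L, length(sample_ids))) {
  data.frame(sample_id = sample_ids, subject_id = subjects,
             body_site = sites, visit = visits, stringsAsFactors = FALSE)
}

# two families under one order, three genera
tiny_lineages <- c(
  "Bacteria|Firmicutes|Bacilli|Lactobacillales|Streptococcaceae|Streptococcus",
  "Bacteria|Firmicutes|Bacilli|Lactobacillales|Streptococcaceae|Lactococcus",
  "Bacteria|Firmicutes|Bacilli|Lactobacillales|Carnobacteriaceae|Granulicatella"
)

tiny_counts <- function(values = rbind(c(3, 10), c(4, 0), c(5, 2)),
                        lineages = tiny_lineages) {
  m <- values
  rownames(m) <- lineages
  colnames(m) <- paste0("samp", seq_len(ncol(m)))
  clade_counts(m, make_meta(colnames(m)))
}

# random genus-depth lineage path generator (for round-trip / propagation)
random_lineages <- function(n, n_phyla = 3, n_per = 2) {
  vapply(seq_len(n), function(i) {
    ph <- sprintf("Phy%d", sample.int(n_phyla, 1))
    cl <- sprintf("%s_c%d", ph, sample.int(n_per, 1))
    or <- sprintf("%s_o%d", cl, sample.int(n_per, 1))
    fa <- sprintf("%s_f%d", or, sample.int(n_per, 1))
    ge <- sprintf("%s_g%d", fa, i)
    paste("Bacteria", ph, cl, or, fa, ge, sep = "|")
  }, character(1))
}

# abundance table built directly from a genus-level relative matrix
abundance_fixture <- function(mat, meta) {
  counts <- round(mat * 1e6)
  storage.mode(counts) <- "double"
  if (is.null(colnames(counts))) colnames(counts) <- meta$sample_id
  x <- clade_counts(counts, meta)
  normalize_abundance(propagate_counts(x))
}

# standard planted-biomarker harness configuration: four groups over the
# ten habitats, shared base composition, 200 exchangeable null genera,
# five planted clades (fold >= 10), one per group plus a second in G1
harness_config <- function(seed, n_subjects = 30) {
  cohort_config(
    n_subjects = n_subjects, composition = "shared",
    n_null_genera = 200, rare_phyla = NULL,
    defective_rate = 0, repeat_visit_rate = 0,
    planted = data.frame(
      name = sprintf("SimGenus%03d", 1:5),
      group = c("G1", "G2", "G3", "G4", "G1"),
      fold = c(10, 12, 15, 10, 20),
      stringsAsFactors = FALSE),
    seed = seed)
}
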