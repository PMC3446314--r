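#' Reference taxonomy used by the cohort simulator
#'
#' A compact RDP-style hierarchy of 38 genera across seven phyla, wired to
#' genus names commonly observed in the adult digestive tract so that
#' simulated reports read naturally. The names carry no data dependency;
#' all abundances come from the generative model.
#'
#' @return `data.frame` with columns `phylum`, `class`, `order`, `family`,
#'   `genus`, `lineage`.
#' @export
default_taxa <- function() {
  t <- rbind(
    c("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Streptococcus"),
    c("Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae", "Gemella"),
    c("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae", "Lactobacillus"),
    c("Firmicutes", "Bacilli", "Lactobacillales", "Carnobacteriaceae", "Granulicatella"),
    c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae", "Veillonella"),
    c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae", "Dialister"),
    c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae", "Megasphaera"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Oribacterium"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Catonella"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Roseburia"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "Coprococcus"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Faecalibacterium"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Ruminococcus"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae", "Oscillibacter"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Eubacteriaceae", "Eubacterium"),
    c("Firmicutes", "Clostridia", "Clostridiales", "Peptococcaceae", "Peptococcus"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae", "Bacteroides"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Prevotella"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Porphyromonas"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Parabacteroides"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Tannerella"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae", "Barnesiella"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae", "Alistipes"),
    c("Bacteroidetes", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae", "Capnocytophaga"),
    c("Proteobacteria", "Betaproteobacteria", "Neisseriales", "Neisseriaceae", "Neisseria"),
    c("Proteobacteria", "Gammaproteobacteria", "Pasteurellales", "Pasteurellaceae", "Haemophilus"),
    c("Proteobacteria", "Gammaproteobacteria", "Pasteurellales", "Pasteurellaceae", "Aggregatibacter"),
    c("Proteobacteria", "Epsilonproteobacteria", "Campylobacterales", "Campylobacteraceae", "Campylobacter"),
    c("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae", "Escherichia"),
    c("Actinobacteria", "Actinobacteria", "Actinomycetales", "Actinomycetaceae", "Actinomyces"),
    c("Actinobacteria", "Actinobacteria", "Actinomycetales", "Corynebacteriaceae", "Corynebacterium"),
    c("Actinobacteria", "Actinobacteria", "Actinomycetales", "Micrococcaceae", "Rothia"),
    c("Actinobacteria", "Actinobacteria", "Bifidobacteriales", "Bifidobacteriaceae", "Bifidobacterium"),
    c("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae", "Atopobium"),
    c("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae", "Fusobacterium"),
    c("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Leptotrichiaceae", "Leptotrichia"),
    c("TM7", "TM7_class_incertae_sedis", "TM7_order_incertae_sedis",
      "TM7_family_incertae_sedis", "TM7_genera_incertae_sedis"),
    c("Spirochaetes", "Spirochaetia", "Spirochaetales", "Spirochaetaceae", "Treponema")
  )
  df <- as.data.frame(t, stringsAsFactors = FALSE)
  names(df) <- c("phylum", "class", "order", "family", "genus")
  df$lineage <- paste("Bacteria", df$phylum, df$class, df$order, df$family,
                      df$genus, sep = "|")
  df
}

# per-group phylum compositions: G1 Firmicutes-dominant, G2 more even with
# elevated Bacteroidetes/Fusobacteria/TM7, G3 elevated Actinobacteria,
# G4 (stool) Bacteroidetes-dominant (> 0.6) with trace Fusobacteria.
group_phylum_weights <- function() {
  rbind(
    G1 = c(Firmicutes = 0.56, Bacteroidetes = 0.12, Proteobacteria = 0.16,
           Actinobacteria = 0.07, Fusobacteria = 0.07, TM7 = 0.01,
           Spirochaetes = 0.01),
    G2 = c(Firmicutes = 0.34, Bacteroidetes = 0.21, Proteobacteria = 0.12,
           Actinobacteria = 0.13, Fusobacteria = 0.12, TM7 = 0.05,
           Spirochaetes = 0.03),
    G3 = c(Firmicutes = 0.24, Bacteroidetes = 0.19, Proteobacteria = 0.13,
           Actinobacteria = 0.30, Fusobacteria = 0.10, TM7 = 0.02,
           Spirochaetes = 0.02),
    G4 = c(Firmicutes = 0.28, Bacteroidetes = 0.66, Proteobacteria = 0.035,
           Actinobacteria = 0.024, Fusobacteria = 1e-4, TM7 = 3e-4,
           Spirochaetes = 6e-4)
  )
}

# within-phylum genus splits; oral groups share splits except Firmicutes,
# where G1 is Streptococcus-dominated and G2 balances Streptococcus and
# Veillonella; the stool split swings to Lachnospiraceae/Ruminococcaceae
# and Bacteroides.
genus_split <- function(phylum, group) {
  oral <- group %in% c("G1", "G2", "G3")
  w <- switch(phylum,
    Firmicutes = if (group == "G1") c(
      Streptococcus = 0.78, Gemella = 0.09, Granulicatella = 0.04,
      Veillonella = 0.05, Lactobacillus = 0.01, Oribacterium = 0.01,
      Catonella = 0.005, Megasphaera = 0.005, Dialister = 0.005,
      Peptococcus = 0.005
    ) else if (group == "G2") c(
      Streptococcus = 0.30, Veillonella = 0.30, Oribacterium = 0.08,
      Catonella = 0.05, Megasphaera = 0.04, Dialister = 0.04,
      Granulicatella = 0.05, Gemella = 0.04, Peptococcus = 0.02,
      Lactobacillus = 0.08
    ) else if (group == "G3") c(
      Streptococcus = 0.40, Veillonella = 0.22, Gemella = 0.10,
      Granulicatella = 0.08, Oribacterium = 0.06, Catonella = 0.05,
      Dialister = 0.04, Lactobacillus = 0.05
    ) else c(
      Faecalibacterium = 0.30, Ruminococcus = 0.18, Roseburia = 0.14,
      Coprococcus = 0.10, Eubacterium = 0.10, Dialister = 0.06,
      Oscillibacter = 0.06, Streptococcus = 0.03, Veillonella = 0.03
    ),
    Bacteroidetes = if (oral) c(
      Prevotella = 0.58, Porphyromonas = 0.18, Capnocytophaga = 0.10,
      Tannerella = 0.10, Barnesiella = 0.02, Alistipes = 0.02
    ) else c(
      Bacteroides = 0.68, Parabacteroides = 0.12, Alistipes = 0.10,
      Prevotella = 0.05, Barnesiella = 0.03, Tannerella = 0.01,
      Porphyromonas = 0.01
    ),
    Proteobacteria = if (oral) c(
      Neisseria = 0.45, Haemophilus = 0.35, Aggregatibacter = 0.10,
      Campylobacter = 0.08, Escherichia = 0.02
    ) else c(
      Escherichia = 0.80, Campylobacter = 0.10, Haemophilus = 0.05,
      Neisseria = 0.03, Aggregatibacter = 0.02
    ),
    Actinobacteria = if (oral) c(
      Actinomyces = 0.40, Rothia = 0.30, Corynebacterium = 0.15,
      Atopobium = 0.12, Bifidobacterium = 0.03
    ) else c(
      Bifidobacterium = 0.70, Atopobium = 0.10, Actinomyces = 0.10,
      Corynebacterium = 0.05, Rothia = 0.05
    ),
    Fusobacteria = c(Fusobacterium = 0.65, Leptotrichia = 0.35),
    TM7 = c(TM7_genera_incertae_sedis = 1),
    Spirochaetes = c(Treponema = 1)
  )
  w / sum(w)
}

#' Configuration for the synthetic digestive-tract cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: ten body
#' habitats falling into four compositional groups, Dirichlet-multinomial
#' subject variability, log-normal sequencing depth, optional planted
#' differentially abundant clades, rare high-prevalence phyla, defective
#' low-coverage samples and repeat visits.
#'
#' @param n_subjects Number of subjects (default 150).
#' @param sites Body-site codes (default the ten digestive tract
#'   habitats).
#' @param group_map Site-to-group map, default [site_groups()].
#' @param composition `"grouped"` (default; the four groups get distinct
#'   Firmicutes:Bacteroidetes-driven base compositions) or `"shared"`
#'   (every group gets the grand-average base; useful for null or
#'   planted-signal harnesses where all remaining clades must be
#'   exchangeable across groups).
#' @param theta Dirichlet concentration controlling subject-to-subject
#'   variability around the group base (default 50, moderate
#'   overdispersion).
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters
#'   (defaults `log(5000)` and 0.4).
#' @param planted Optional `data.frame` with columns `name` (genus name or
#'   full lineage), `group`, `fold` (> 0): in samples of that group the
#'   clade's base abundance is multiplied by `fold` and the composition
#'   renormalized.
#' @param rare_phyla `data.frame` with `name`, `presence_prob`, `ab_min`,
#'   `ab_max`: per-subject presence draws for low-abundance,
#'   high-prevalence phyla; default a single `SR1`-like phylum present in
#'   65% of subjects at 0.1-1% abundance.
#' @param n_null_genera Extra exchangeable genera (equal base weight in
#'   every group) appended under a clearly synthetic lineage block;
#'   default 0.
#' @param null_weight Total base-composition fraction allotted to the null
#'   block when `n_null_genera > 0` (default 0.3).
#' @param defective_rate Probability that a sample is emitted with read
#'   depth scaled by `defective_depth_factor`, far below the 1% coverage
#'   rule (default 0.02).
#' @param defective_depth_factor Depth multiplier for defective samples
#'   (default 0.001).
#' @param repeat_visit_rate Probability that a (subject, site) pair also
#'   contributes a second-visit sample (default 0.1).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 150,
                          sites = names(site_groups()),
                          group_map = site_groups(),
                          composition = c("grouped", "shared"),
                          theta = 50,
                          depth_meanlog = log(5000),
                          depth_sdlog = 0.4,
                          planted = NULL,
                          rare_phyla = data.frame(
                            name = "SR1", presence_prob = 0.65,
                            ab_min = 0.001, ab_max = 0.01,
                            stringsAsFactors = FALSE),
                          n_null_genera = 0,
                          null_weight = 0.3,
                          defective_rate = 0.02,
                          defective_depth_factor = 0.001,
                          repeat_visit_rate = 0.1,
                          seed = 1) {
  composition <- match.arg(composition)
  stopifnot(n_subjects >= 1, theta > 0,
            defective_rate >= 0, defective_rate <= 1,
            repeat_visit_rate >= 0, repeat_visit_rate <= 1,
            n_null_genera >= 0, null_weight >= 0, null_weight < 1)
  if (!is.null(planted)) {
    stopifnot(all(c("name", "group", "fold") %in% names(planted)),
              all(planted$fold > 0),
              all(planted$group %in% unique(unname(group_map))))
  }
  if (!is.null(rare_phyla) && nrow(rare_phyla)) {
    stopifnot(all(rare_phyla$presence_prob >= 0),
              all(rare_phyla$presence_prob <= 1),
              all(rare_phyla$ab_min > 0),
              all(rare_phyla$ab_max >= rare_phyla$ab_min))
  }
  miss <- setdiff(sites, names(group_map))
  if (length(miss)) stop("sites without group assignment: ",
                         paste(miss, collapse = ", "))
  structure(list(
    n_subjects = n_subjects, sites = sites, group_map = group_map,
    composition = composition, theta = theta,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    planted = planted, rare_phyla = rare_phyla,
    n_null_genera = n_null_genera, null_weight = null_weight,
    defective_rate = defective_rate,
    defective_depth_factor = defective_depth_factor,
    repeat_visit_rate = repeat_visit_rate, seed = seed
  ), class = "cohort_config")
}

# genus-level base composition per group (named by full lineage)
cohort_base_compositions <- function(config) {
  taxa <- default_taxa()
  if (config$n_null_genera > 0) {
    nn <- config$n_null_genera
    fam <- sprintf("SimFamily%02d", ((seq_len(nn) - 1) %% 10) + 1)
    null <- data.frame(
      phylum = "SimPhylum", class = "SimClass", order = "SimOrder",
      family = fam, genus = sprintf("SimGenus%03d", seq_len(nn)),
      stringsAsFactors = FALSE)
    null$lineage <- paste("Bacteria", null$phylum, null$class, null$order,
                          null$family, null$genus, sep = "|")
    taxa <- rbind(taxa, null)
  }
  groups <- rownames(group_phylum_weights())
  pw <- group_phylum_weights()
  base <- matrix(0, nrow(taxa), length(groups),
                 dimnames = list(taxa$lineage, groups))
  for (g in groups) {
    for (ph in colnames(pw)) {
      split <- genus_split(ph, g)
      rows <- taxa$phylum == ph & taxa$genus %in% names(split)
      base[rows, g] <- pw[g, ph] * split[taxa$genus[rows]]
    }
  }
  base <- sweep(base, 2L, colSums(base), "/")
  if (config$n_null_genera > 0) {
    null_rows <- taxa$phylum == "SimPhylum"
    base[!null_rows, ] <- base[!null_rows, , drop = FALSE] *
      (1 - config$null_weight)
    base[null_rows, ] <- config$null_weight / sum(null_rows)
  }
  if (config$composition == "shared") {
    avg <- rowMeans(base)
    base[] <- avg
  }
  base
}

rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
  s <- sum(x)
  if (s == 0) stop("degenerate Dirichlet draw: all concentrations zero")
  x / s
}

#' Generate a synthetic multi-site 16S cohort with ground truth
#'
#' For every subject and body habitat, a community composition is drawn
#' from `Dirichlet(theta * base_g)` around the habitat group's base
#' composition (with planted biomarkers' components fold-multiplied and
#' renormalized in their target group), rare phyla are injected for the
#' subjects carrying them, and read counts are drawn multinomially at a
#' log-normal depth. A configurable fraction of samples is emitted
#' "defective" (depth far below the 1% coverage rule) and a fraction of
#' subject-site pairs contributes a second-visit sample. Everything is
#' deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `counts` (a genus-level [clade_counts()] table) and
#'   `truth` (class `cohort_truth`): group base compositions, resolved
#'   planted biomarkers, defective sample IDs, rare-phylum presence per
#'   subject, and the drawn depths.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  base <- cohort_base_compositions(config)
  lineages <- rownames(base)

  # append rare phyla (base weight zero; injected post-Dirichlet so their
  # presence/absence is governed by the per-subject draw, not sampling noise)
  rare <- config$rare_phyla
  rare_lineages <- character(0)
  if (!is.null(rare) && nrow(rare)) {
    rare_lineages <- paste("Bacteria", rare$name,
                           paste0(rare$name, "_class_incertae_sedis"),
                           paste0(rare$name, "_order_incertae_sedis"),
                           paste0(rare$name, "_family_incertae_sedis"),
                           paste0(rare$name, "_genera_incertae_sedis"),
                           sep = "|")
    base <- rbind(base, matrix(0, length(rare_lineages), ncol(base),
                               dimnames = list(rare_lineages, colnames(base))))
    lineages <- rownames(base)
  }

  planted <- resolve_planted(config$planted, lineages)
  subjects <- sprintf("S%03d", seq_len(config$n_subjects))

  rare_presence <- NULL
  rare_ab <- NULL
  if (length(rare_lineages)) {
    rare_presence <- matrix(
      stats::runif(config$n_subjects * nrow(rare)) < rep(rare$presence_prob,
                                                         each = config$n_subjects),
      nrow = config$n_subjects,
      dimnames = list(subjects, rare$name))
    rare_ab <- matrix(
      stats::runif(config$n_subjects * nrow(rare),
                   min = rep(rare$ab_min, each = config$n_subjects),
                   max = rep(rare$ab_max, each = config$n_subjects)),
      nrow = config$n_subjects,
      dimnames = list(subjects, rare$name))
  }

  # per-group generating base with planted folds applied
  group_base <- base
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      g <- planted$group[i]
      group_base[planted$lineage[i], g] <-
        group_base[planted$lineage[i], g] * planted$fold[i]
    }
    group_base <- sweep(group_base, 2L, colSums(group_base), "/")
  }

  # sample plan: visit 1 everywhere, visit 2 for a random subset
  plan <- expand.grid(subject_id = subjects, body_site = config$sites,
                      stringsAsFactors = FALSE)
  plan <- plan[order(plan$subject_id, plan$body_site), , drop = FALSE]
  second <- stats::runif(nrow(plan)) < config$repeat_visit_rate
  plan1 <- cbind(plan, visit = 1L)
  plan <- if (any(second)) {
    rbind(plan1, cbind(plan[second, , drop = FALSE], visit = 2L))
  } else plan1
  plan$sample_id <- sprintf("%s_%s_V%d", plan$subject_id, plan$body_site,
                            plan$visit)
  plan <- plan[order(plan$subject_id, plan$body_site, plan$visit), ,
               drop = FALSE]

  n_samp <- nrow(plan)
  depth <- pmax(50, round(stats::rlnorm(n_samp, config$depth_meanlog,
                                        config$depth_sdlog)))
  defective <- stats::runif(n_samp) < config$defective_rate
  depth[defective] <- pmax(3, round(depth[defective] *
                                      config$defective_depth_factor))

  counts <- matrix(0L, length(lineages), n_samp,
                   dimnames = list(lineages, plan$sample_id))
  for (s in seq_len(n_samp)) {
    g <- unname(config$group_map[plan$body_site[s]])
    comp <- rdirichlet1(config$theta * group_base[, g])
    if (length(rare_lineages)) {
      subj <- plan$subject_id[s]
      carried <- rare_presence[subj, ]
      if (any(carried)) {
        add <- ifelse(carried, rare_ab[subj, ], 0)
        comp <- comp * (1 - sum(add))
        comp[match(rare_lineages, lineages)] <- add
      }
    }
    counts[, s] <- stats::rmultinom(1L, size = depth[s], prob = comp)
  }

  meta <- plan[, c("sample_id", "subject_id", "body_site", "visit")]
  rownames(meta) <- NULL
  truth <- structure(list(
    config = config,
    base = base,
    group_base = group_base,
    planted = planted,
    defective_samples = plan$sample_id[defective],
    rare_presence = rare_presence,
    rare_lineages = rare_lineages,
    depth = stats::setNames(depth, plan$sample_id)
  ), class = "cohort_truth")
  list(counts = clade_counts(counts, meta), truth = truth)
}

resolve_planted <- function(planted, lineages) {
  if (is.null(planted) || !nrow(planted)) return(NULL)
  lineage <- character(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    nm <- planted$name[i]
    hit <- if (nm %in% lineages) nm else
      lineages[grepl(paste0("\\|", nm, "$"), lineages)]
    if (length(hit) != 1L)
      stop("planted clade does not resolve uniquely: ", nm)
    lineage[i] <- hit
  }
  data.frame(name = planted$name, lineage = lineage,
             group = planted$group, fold = planted$fold,
             stringsAsFactors = FALSE)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d subjects, %d sites, %d planted biomarkers, %d defective samples\n",
              x$config$n_subjects, length(x$config$sites),
              if (is.null(x$planted)) 0L else nrow(x$planted),
              length(x$defective_samples)))
  invisible(x)
}

#' Generate gene-family abundances paired to a synthetic cohort
#'
#' Emits a KEGG-Orthology-style table for (a subset of) the cohort's
#' samples. Linked gene families are a monotone function of one clade's
#' relative abundance plus Gaussian noise (scaled by the clade's
#' cross-sample standard deviation, truncated at zero); unlinked families
#' are independent log-normal noise. Supports validation of the
#' clade-gene-family correlation analysis against known truth.
#'
#' @param cohort Output of [generate_cohort()] (or a [clade_counts()]
#'   table).
#' @param links Optional `data.frame` with columns `clade` (genus name or
#'   lineage), `gene_family` (KO identifier), `noise_sd` (noise scale in
#'   units of the clade's abundance SD; 0 = deterministic link).
#' @param n_families Total gene families emitted, linked ones included
#'   (default 20).
#' @param coverage Fraction of cohort samples with metagenomic data
#'   (default 1).
#' @param seed Integer seed.
#' @return A [gene_table()] whose sample IDs carry a `_wgs` suffix but
#'   share subject and body site with the 16S samples.
#' @export
generate_paired_genes <- function(cohort, links = NULL, n_families = 20,
                                  coverage = 1, seed = 1) {
  counts <- if (inherits(cohort, "clade_counts")) cohort else cohort$counts
  set.seed(seed)
  tot <- colSums(counts$counts)
  ab <- sweep(counts$counts, 2L, pmax(tot, 1), "/")
  keep <- sort(sample(ncol(ab), max(2L, round(coverage * ncol(ab)))))
  ab <- ab[, keep, drop = FALSE]
  meta16 <- counts$meta[keep, , drop = FALSE]
  n <- ncol(ab)

  if (!is.null(links)) {
    stopifnot(all(c("clade", "gene_family", "noise_sd") %in% names(links)))
    links$lineage <- vapply(links$clade, function(nm) {
      hit <- if (nm %in% rownames(ab)) nm else
        rownames(ab)[grepl(paste0("\\|", nm, "$"), rownames(ab))]
      if (length(hit) != 1L) stop("link clade does not resolve uniquely: ", nm)
      hit
    }, character(1))
  }
  n_linked <- if (is.null(links)) 0L else nrow(links)
  if (n_families < n_linked) n_families <- n_linked
  kos <- c(if (n_linked) links$gene_family,
           sprintf("K%05d", 10000L + seq_len(n_families - n_linked)))
  g <- matrix(0, n_families, n, dimnames = list(kos, NULL))
  for (i in seq_len(n_families)) {
    if (i <= n_linked) {
      x <- ab[links$lineage[i], ]
      y <- x + stats::rnorm(n, 0, links$noise_sd[i] * stats::sd(x))
      g[i, ] <- pmax(y, 0)
    } else {
      g[i, ] <- stats::rlnorm(n, meanlog = -9, sdlog = 1)
    }
  }
  colnames(g) <- paste0(meta16$sample_id, "_wgs")
  gene_meta <- data.frame(sample_id = colnames(g),
                          subject_id = meta16$subject_id,
                          body_site = meta16$body_site,
                          stringsAsFactors = FALSE)
  gene_table(g, gene_meta)
}
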