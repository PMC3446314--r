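Package: tractome
Title: Digestive Tract 16S rRNA Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for multi-site 16S rRNA clade-abundance
    surveys of the human digestive tract. Propagates read counts through an
    RDP-style taxonomy so every analysis can run from phylum to genus,
    applies hierarchical quality control (taxon support filtering,
    low-coverage sample removal, first-visit deduplication) and per-rank
    normalization, computes Bray-Curtis beta diversity, inverse Simpson
    alpha diversity, four-group community-structure summaries with
    statistical support and classical MDS ordination, discovers biomarker
    clades with a Kruskal-Wallis / pairwise Wilcoxon / bootstrapped linear
    discriminant effect-size procedure, profiles taxon prevalence,
    variability and Firmicutes:Bacteroidetes ratios, correlates clade and
    gene-family abundances with Benjamini-Hochberg FDR control, and ships a
    Dirichlet-multinomial cohort simulator with a ground-truth ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
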