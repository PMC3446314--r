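# tractome

Analysis toolkit for multi-site 16S rRNA surveys of the human digestive
tract microbiome.

Ten body habitats line the adult digestive tract — buccal mucosa (BM),
keratinized gingiva (KG), hard palate (HP), saliva (Sal), tongue dorsum
(TD), palatine tonsils (PT), throat (Th), supra- and sub-gingival plaque
(SupP, SubP) and stool — and their bacterial communities fall into four
compositional groups distinguished chiefly by the Firmicutes:Bacteroidetes
balance (G1 = BM/KG/HP, G2 = Sal/TD/PT/Th, G3 = plaques, G4 = stool).
`tractome` implements, as tested reusable functions, the full analysis
stack needed to characterize such a cohort from a clade-by-sample read
count table:

* **Taxonomy handling** — RDP-style lineage strings (`parse_lineage()`)
  and propagation of read counts to every ancestor clade
  (`propagate_counts()`), with `unclassified` placeholder bins so column
  sums are conserved at every rank from phylum to genus.
* **Quality control** (`qc_pipeline()`) — dataset-level taxon support
  filtering (≥ 2 reads in ≥ 2 samples), removal of low-coverage samples
  (top taxon count < 1 % of that taxon's dataset maximum), first-visit
  deduplication, and per-rank normalization to relative abundances.
* **Community structure** — Bray–Curtis beta diversity
  (BC(p, q) = Σ|p − q| / Σ(p + q)), within/between-group similarity
  summaries with statistical support, classical MDS ordination, and
  inverse Simpson alpha diversity (D = 1/Σp²) with group contrasts.
* **Biomarker discovery** (`run_lefse()`) — an LDA-effect-size procedure:
  Kruskal–Wallis screen (α = 0.05), pairwise Wilcoxon
  biological-consistency check, and bootstrapped linear-discriminant
  effect sizes on a log₁₀ scale with a pass threshold of 2, run on all
  clades at all ranks simultaneously, with all-against-all and
  one-against-rest strategies.
* **Prevalence and variability** — per-site / upper-tract / stool
  prevalence over fully sampled subjects, coefficient-of-variation
  rankings, same-subject oral–stool overlap lists, and
  Firmicutes:Bacteroidetes ratios.
* **Function integration** (`spearman_correlate()`) — Spearman
  correlation of clade abundances against KEGG-Orthology gene-family
  tables per body site, with Benjamini–Hochberg FDR control.
* **Synthetic cohorts** (`generate_cohort()`) — a Dirichlet-multinomial
  simulator of the whole study design (four groups, planted biomarkers,
  rare high-prevalence phyla, defective samples, repeat visits) with a
  ground-truth ledger, so every stage is testable without any download.

## Worked example

```r
library(tractome)

cohort <- generate_cohort(cohort_config(n_subjects = 40, seed = 42))
qc <- qc_pipeline(cohort$counts)
qc$report
#> <qc_report> removed 0 taxa, 54 samples; retained 107 taxa, 390 samples
#> low_coverage repeat_visit
#>           13           41

D <- bray_curtis_matrix(qc$abundance)          # genus-level Bray-Curtis
groups <- sample_groups(qc$abundance$meta)     # G1..G4 via body site
group_structure_summary(D, groups)
#> <group_structure> mean similarity (sd):
#>    G1          G2          G3          G4
#> G1 0.73 ± 0.05 0.47 ± 0.07 0.47 ± 0.06 0.08 ± 0.03
#> G2 0.47 ± 0.07 0.64 ± 0.06 0.59 ± 0.06 0.09 ± 0.04
#> G3 0.47 ± 0.06 0.59 ± 0.06 0.66 ± 0.06 0.10 ± 0.04
#> G4 0.08 ± 0.03 0.09 ± 0.04 0.10 ± 0.04 0.74 ± 0.05

round(tapply(alpha_diversity(qc$abundance), groups, mean), 1)
#>   G1   G2   G3   G4
#>  4.6 12.6 12.4  4.6

biomarkers <- run_lefse(qc$abundance, groups, seed = 1)
head(biomarkers[, c("feature", "rank", "enriched_class", "effect_size")], 4)
#>                                                                       feature   rank enriched_class effect_size
#> 1  Bacteria|Firmicutes|Bacilli|Lactobacillales|Streptococcaceae|Streptococcus  genus             G1    5.404530
#> 2                Bacteria|Firmicutes|Bacilli|Lactobacillales|Streptococcaceae family             G1    5.404530
#> 3             Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Bacteroidaceae family             G4    5.402605
#> 4 Bacteria|Bacteroidetes|Bacteroidia|Bacteroidales|Bacteroidaceae|Bacteroides  genus             G4    5.402605
```

Reading the output: QC dropped the 13 under-sequenced samples and 41
repeat visits the generator emitted; every diagonal (within-group) mean
similarity exceeds the off-diagonal cells in its row, i.e. the four
habitat groups form distinct community structures; alpha diversity is low
in the Streptococcus-dominated G1 mouth surfaces and the
Bacteroides-dominated stool, high in the more even saliva/tongue and
plaque groups; and the top-ranked biomarkers are *Streptococcus* (with its
family) for G1 and *Bacteroides* for stool, each with a log₁₀ effect size
well above the pass threshold of 2.

Real data enter through `read_clade_counts(counts_tsv, meta_tsv)`: a TSV
with full lineage strings in the first column and one integer column per
sample, plus a metadata TSV (`sample_id`, `subject_id`, `body_site`,
`visit`). Gene-family tables for `spearman_correlate()` are TSVs with KO
identifiers as rows.

## Vignette

`vignettes/digestive-tract-analysis.Rmd` documents the models,
parameter choices, numerical conventions and known limitations.
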