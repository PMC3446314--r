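---
title: "Methods: multi-site digestive tract 16S community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-site digestive tract 16S community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tractome` analyses clade-by-sample 16S rRNA read-count tables from
multi-site body-habitat surveys: ten digestive tract habitats per subject,
grouped into four community types (G1 mouth surfaces, G2
saliva/tongue/tonsils/throat, G3 dental plaques, G4 stool). This vignette
is the package's own account of the models it implements, the parameters
that matter, the numerical conventions adopted where the choices were
genuinely open, and what the synthetic validation does and does not show
about real data.

## Taxonomy and count propagation

Phylotype classifiers assign reads at six ranks (domain, phylum, class,
order, family, genus); species-level identification is not attempted
because short amplicon reads do not support it. `propagate_counts()`
produces one row per clade at every rank, each internal clade carrying the
sum of reads assigned to it directly plus all descendants. Reads whose
classification stopped above genus are carried down through
`unclassified` placeholder nodes, one per parent, so that at *every* rank
the column sum equals the sample's total assigned reads. This conservation
property is what makes per-rank normalization well defined and lets the
biomarker scan treat all ranks as one feature set. Homonymous clade names
are always disambiguated by the full lineage path, never by the leaf name.
Propagation is idempotent: a propagated table is returned unchanged.

## Quality control

The pipeline order is fixed: taxon support filter → low-coverage sample
filter → first-visit deduplication → normalization. Re-running the
pipeline on its own output changes nothing.

* **Taxon support.** A clade is kept only if supported by at least 2
  reads in each of at least 2 samples (`min_reads`, `min_samples`,
  default 2/2). The phrase "two sequences in two samples" admits a weaker
  reading — at least 2 reads in total spread over at least 2 samples —
  which is available as `rule = "total"`; the stricter per-sample reading
  is the default. Removed clades' reads are dropped, not reassigned, so
  downstream abundances are relative to retained taxa.
* **Sample coverage.** For each sample, the read count of its most
  abundant taxon *t* is compared with the maximum count *t* reaches in
  any sample; the sample is discarded when the former is strictly below
  1 % of the latter (`fraction = 0.01`). The comparison needs a fixed
  rank to be meaningful across samples; the default is the finest
  classified rank present (genus), configurable via `rank`. All-zero
  samples are discarded unconditionally.
* **Visits.** For every (subject, body site) pair only the sample with
  the minimum visit number is retained — the minimum present rather than
  literally visit 1, so cohorts whose first time point failed upstream QC
  are not emptied. Duplicate (subject, site, visit) triples raise an
  error rather than being silently resolved.
* **Normalization.** Within each sample and rank, counts are divided by
  the sample's rank total. A zero rank total signals an upstream QC
  failure and errors out rather than producing NaNs.

## Beta/alpha diversity and the four-group structure

Bray–Curtis dissimilarity BC(p, q) = Σ|p−q| / Σ(p+q) is computed on
genus-level profiles by default — the finest reliably classified rank —
with `rank` exposed because coarser choices are defensible; the matrix
computation is delegated to `vegan::vegdist` and cross-checked against the
formula in the tests. Bray–Curtis is a semimetric (no triangle
inequality), which is why ordination uses classical (Torgerson) MDS on
the double-centered squared dissimilarities (`stats::cmdscale`) rather
than a metric embedding.

Group structure is summarized as the mean ± sd of *similarity*
(1 − dissimilarity) over all within-group pairs (diagonal) and cross-group
pairs (off-diagonal). Similarity is the reporting default because "higher
= more alike" reads naturally in a summary table; the dissimilarity
representation is one flag away. Statistical support for each group
compares its pooled within-group distances against its pooled distances to
all other samples with a Welch t-test by default; because pairwise
distances sharing a sample are not independent, a label-permutation
alternative (`method = "permutation"`) is provided and used in the test
suite's null calibration. Alpha diversity is the inverse Simpson index
1/Σp², an evenness-sensitive effective taxon count; group contrasts use
Welch's t-test, with the convention that contrasting a group with itself
returns p = 1.

## Biomarker discovery

The effect-size procedure runs three stages per feature (every clade at
every rank):

1. **Significance screen**: Kruskal–Wallis with midrank tie correction at
   `alpha = 0.05`. Features with identical values short-circuit to p = 1.
2. **Biological consistency**: the candidate enriched class is the class
   with the highest mean abundance; unpaired Wilcoxon rank-sum tests
   between the candidate and each other class must all be significant at
   `alpha` *and* agree in direction. Rank-sum p-values use the normal
   approximation with midranks and continuity correction uniformly —
   abundance data are tie-rich, so the exact distribution is unavailable
   in general, and a single approximation keeps behaviour continuous in
   the sample size.
3. **Effect size**: abundances are rescaled to parts-per-million and, for
   each of `n_boot = 30` bootstrap rounds, a two-thirds per-class
   subsample is drawn and a two-class linear discriminant (enriched class
   vs pooled complement) is fitted over all surviving features jointly.
   A feature's discrimination magnitude is the average of its absolute
   raw class-mean difference and its share of the discriminant-axis
   separation; round averages are reported as log10(1 + magnitude). On
   this scale the customary pass threshold of 2 corresponds to a ~100 ppm
   class difference, and dominant clades score 4–6.

Two multi-class strategies are exposed. `all_against_all` (default)
screens with the multi-class Kruskal–Wallis test; `one_against_rest`
pools the complement into one class for the significance stage of the
focal class — a slightly more stringent setting — while consistency is
still required against each remaining class individually. In both cases a
genus-level signal necessarily surfaces in its ancestors too (their
abundances contain it by construction); reporting the whole lineage is
intended behaviour, not duplication.

Numerical choices: the discriminant direction is a Fisher solve against
the pooled within-class covariance with a small ridge
(1e-6 × mean diagonal) because constant-within-class features — the norm
for sparse clades after subsampling — make the scatter matrix singular;
classical LDA routines refuse such inputs outright. Candidate-class ties
resolve to the first factor level and result ordering breaks effect-size
ties by feature name, so records are fully deterministic given the seed.
No multiple-testing correction is applied across features by default: the
procedure's selectivity comes from stacking the screen, the consistency
gate and the effect-size floor, mirroring standard practice for this
method. A consequence worth knowing: the composite gate's empirical
per-feature null pass rate is roughly 0.3–0.5 % at α = 0.05 (measured on
exchangeable null clades in the test harness), so a scan of hundreds of
null features should be expected to yield a few spurious biomarkers —
about 1 per 200 truly null clades per cohort — while planted 10-fold
signals are recovered essentially always. Users needing strict FDR
control can adjust `alpha` or post-filter on `kw_p`.

## Prevalence, variability, composition

"Detected" means abundance > 0 after QC, i.e. at least one retained read;
a configurable floor is available because the effective limit of
detection is set by sequencing depth. Prevalence denominators use only
subjects sampled at all ten habitats (the completeness criterion), so
per-site, upper-tract (OR over the nine non-stool sites) and stool scopes
are comparable. The coefficient of variation uses the sample (n−1)
standard deviation over all samples of all sites pooled; the variability
report includes clades present above 0.001 % in at least half the
samples, ranked most-stable first. Oral–stool overlap requires
same-subject presence in ≥ 1 upper-tract site *and* stool in at least
45 % of complete subjects by default. Firmicutes:Bacteroidetes ratios are
ratios of phylum mean abundances per site or group, with an `Inf`
sentinel when the denominator is empty.

## Clade–gene-family correlation

Gene-family (KEGG-Orthology-style) tables are consumed as given —
functional reconstruction is upstream of this package. 16S and
metagenomic samples are inner-joined on (subject, body site); sites with
fewer than 10 pairs are flagged. Spearman's rho with midranks is computed
per (clade, KO, site), with two-sided p-values from the t approximation
and Benjamini–Hochberg adjustment *within each body site's* family of
tests (a global family is a one-flag change). Constant vectors are
skipped and counted rather than yielding undefined correlations. Genus
through phylum ranks are tested; OTU-level phylotypes are outside this
package's resolution.

## The synthetic cohort generator

`generate_cohort()` draws, for each subject × site, a composition from
Dirichlet(θ · base_g) around the site group's base composition, then
counts from a multinomial at log-normal depth. Its defaults define the
study conditions the package is validated under:

* **Base compositions** follow the four-group pattern: G1
  Firmicutes-dominant (Streptococcus-led), G2 more even with elevated
  Bacteroidetes/Fusobacteria/TM7, G3 with elevated Actinobacteria, G4
  Bacteroidetes-dominant (> 0.6) with trace Fusobacteria. 38 genera
  across 7 phyla carry real taxon names so reports read naturally; the
  names carry no data dependency.
* **θ = 50**: moderate subject-to-subject overdispersion; clade-level
  CVs of 0.3–4, matching the wide variability observed in habitat
  surveys. `composition = "shared"` gives every group the grand-average
  base — the exchangeable-null setting used for biomarker
  false-positive measurement.
* **Depth** ~ lognormal(log 5000, 0.4), the scale of multi-region
  pyrosequencing phylotype tables.
* **Planted biomarkers** multiply one clade's base by a fold in one group
  and renormalize; note renormalization necessarily perturbs all other
  clades' expected abundances by the planted mass (a compositional fact,
  not a bug), which is why the null-clade block keeps planted mass below
  ~5 %.
* **Rare phyla** (default one SR1-like phylum, presence probability
  0.65, abundance 0.1–1 %) are injected after the Dirichlet draw for the
  subjects carrying them, so measured prevalence tracks the presence
  probability rather than being diluted by sampling noise at tiny
  concentrations.
* **Defective samples** (rate 0.02) have depth scaled by 1e-3, placing
  them far below the 1 % coverage rule by construction; **repeat visits**
  (rate 0.1) add second-visit samples for random subject-site pairs.

What the generator does *not* emulate: chimeras and sequencing error,
PCR/primer bias, within-subject temporal drift, phylogenetic correlation
between clades beyond the shared hierarchy, and OTU-level structure.
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean compositional model, not robustness to upstream
artefacts.

## Validation scales

The test suite and `scripts/acceptance.R` exercise the stack at the
following sizes, chosen to make every property measurable at comfortable
statistical resolution: group-structure recovery on 150 subjects × 10
sites (~1,500 samples); biomarker recovery on 20 independent cohorts of
30 subjects with 5 planted clades (fold 10–20) among 200 exchangeable
nulls; Kruskal–Wallis null calibration on 1,000 simulated features;
correlation recovery over 50 (tests) or 10 (script) seeds of 30 paired
samples. Oracle-equivalence checks compare every core statistic with an
independent brute-force implementation on ≥ 20 random fixtures at 1e-8.

## Known limitations

* Welch t-tests on pooled pairwise distances overstate significance
  because distance pairs are dependent; prefer the permutation method for
  publishable p-values (the default mirrors common reporting practice).
* The effect-size scale (ppm, log10(1 + ·)) is a convention; scores are
  comparable within a run, not across differently normalized datasets.
* BH adjustment is per body site; correlations pooled across sites need
  the global-family flag.
* The discriminant's ridge makes effect sizes insensitive to exact
  collinearity but slightly shrinks coefficients for near-singular
  feature sets.
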