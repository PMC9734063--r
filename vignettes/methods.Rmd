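---
title: "Models and design choices in regionomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in regionomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`regionomics` implements a complete multi-region, multi-omics
differential-analysis stack for two-condition (sham vs treated) brain
studies, together with synthetic-data generators that plant and record
ground truth. This vignette explains the statistical models, the
tunable parameters and their defaults, what the generators do and do
not emulate, and the design decisions taken where several reasonable
options existed.

## The study design being emulated

The generators reproduce the structure of multi-region antidepressant
studies: 27 brain regions, each profiled by bulk RNA-seq in 4
replicates per condition (216 transcriptomes in all), H3K27ac ChIP-seq
quantified over a shared consensus peak set in 2 replicates per
condition per region, and scRNA-seq of two hippocampal regions (dorsal
and ventral dentate gyrus) with 5 replicates per condition and on the
order of a dozen cell types. Sample sizes are design facts; count
depths, dispersions and effect sizes are the package's own calibration
choices, discussed below.

## Bulk counts and the differential engine

Counts are modelled negative-binomially with variance
$\mu + \alpha\mu^2$. The generator draws per-gene baseline means
log-normal(log 100, 1), per-gene dispersions $\alpha \sim$
Gamma(shape 2, mean 0.1) — typical bulk RNA overdispersion — and
per-sample size factors log-normal(0, 0.2), so that normalization is
non-trivial. A planted module multiplies the treated mean of its genes
by $2^{\text{effect}}$ in the affected regions; every per-gene,
per-region effect is recorded in the truth table.

`estimate_size_factors()` is the median of ratios to per-feature
geometric means, over features with no zero count, rescaled to
geometric mean one. `test_differential()` then:

1. estimates a per-feature dispersion by method of moments from the
   pooled within-condition variances of normalized counts;
2. fits a mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ by
   gamma-family regression (falling back to the median dispersion when
   the fit is degenerate) and shrinks each moment estimate 50/50 toward
   the trend;
3. forms the Wald statistic $\widehat{\mathrm{lfc}}/\mathrm{se}$, where
   $\widehat{\mathrm{lfc}} = \log_2\frac{\bar m_T + 0.5}{\bar m_S + 0.5}$
   on normalized condition means and the standard error comes from the
   NB variance by the delta method;
4. refers the statistic to a t distribution with
   $2(n_T + n_S - 2)$ degrees of freedom. The doubling reflects the
   equal-weight shrinkage toward the trend: an equal-weight prior
   contributes roughly as many degrees of freedom as the residual
   moment estimate. In calibration runs a normal reference produced
   spurious Benjamini–Hochberg calls in a third or more of global-null
   simulations, while the moderated-t reference produced essentially
   none and retained the required power on planted effects;
5. applies BH per region and per modality, and assigns `up`/`down`
   status at $|\mathrm{lfc}| \ge \log_2 1.25$ and $q \le 0.1$ — the
   thresholds used for both DEGs and differentially acetylated (DA)
   peaks throughout. Features with all-zero counts are reported `ns`
   with absent p and q.

Two caveats are worth stating. First, the fixed pseudocount interacts
with the geometric-mean convention: multiplying one sample's counts by
$c$ drifts the normalized scale by $c^{1/m}$, so fold-changes are
invariant only to about $10^{-3}$ at typical counts, not exactly.
Second, the power of this (or any) per-feature test at 4 vs 4
replicates is bounded: at dispersion 0.1 and mean 200 a one-unit log2
effect carries a Wald signal of about 3 standard errors, which cannot
yield 80% sensitivity at FDR 0.1 when true features are a small
minority of a large matrix. The planted-recovery calibration therefore
uses 200 planted features (100 up, 100 down, so median-of-ratios
normalization keeps its anchor) alongside a 50-feature null
complement: large enough to make the false-discovery proportion a
meaningful quantity, small enough that the stated sensitivity is
attainable.

## The ChIP layer

`simulate_chip()` lays genes on one synthetic chromosome at 50 kb
spacing, places one promoter peak per gene with its centre within
±1 kb of the TSS, and adds distal decoy peaks at least 10 kb from any
TSS (so promoter assignment is unambiguous in tests). Promoter-peak
log2 effects are drawn with correlation $\rho$ to the gene's
expression effect in the same region ($\rho = 1$ copies the effect
exactly; regions with no planted expression variance stay null), and
decoys are null. Peak counts reuse the NB machinery with a baseline
mean of ~3,000 reads and dispersion Gamma(2, mean 0.005): consensus
H3K27ac peaks aggregate signal over wide intervals and replicate very
reproducibly, and a 2-replicate design (4 residual degrees of freedom)
only resolves differential acetylation in that deep, low-dispersion
regime — with bulk-RNA-like dispersion the same design calls nothing
at $q \le 0.1$, which is the package's explicit reading of how a
2-replicate ChIP arm can report thousands of DA peaks.

## Modules and sharing

`build_foldchange_matrix()` collects the union of region-wise
differential features; untested entries enter as 0 ("no evidence of
change") with a companion mask whose per-module counts are reported.
`cluster_modules()` runs k-means with k-means++ seeding and Lloyd
iterations, best of 25 restarts by inertia, on the raw (unscaled)
log2 fold-change rows: sign and magnitude across regions are the
biology that separates globally up-regulated modules from
region-specific ones, so rows are deliberately not z-scored
(`scale_rows = TRUE` is available). `k` defaults to 8 for genes and
peaks alike, matching the module count displayed for both modalities
in the studies this package models; module labels are made stable by
relabelling on module size. `sharing_summary()` counts, per feature,
the regions where it is up and where it is down, and reports the
fractions of the union at sharing degree one and three or more.

## Enrichment statistics

* **ORA**: exact hypergeometric upper tail with fold-enrichment
  $(k/n)/(K/N)$ and BH across the collection. The universe is the set
  of features actually tested in that region, not the whole genome,
  guarding against detection bias.
* **GSEA**: the weighted Kolmogorov–Smirnov running sum (hits
  increment by $|s|^w$ normalized over the set, $w = 1$; misses
  decrement $1/(N-K)$); the ES is the extremum of the running sum,
  ties broken toward the positive deviation. The null permutes gene
  labels, not phenotypes: with four replicates per condition a
  phenotype permutation null is too coarse to be useful. NES divides
  the ES by the mean |ES| of same-sign permutations; p is one-sided by
  sign with the +1 correction.
* **GREAT-style enrichment**: each gene's regulatory domain is its
  basal domain (TSS ± 5 kb) extended up to 100 kb or to the nearest
  neighbouring basal domain, whichever is closer — a fully specified
  simplification of GREAT's association rule, since the exact rule
  behind the figures this emulates is not published in the main text.
  A peak belongs to a domain iff its midpoint falls inside (peaks
  spanning borders are not double-counted), and the binomial tail uses
  the domain union's genome fraction as $p_0$.

## Integration

Peaks map to the gene with the nearest TSS within a 2 kb window of the
peak midpoint, strand-ignored (H3K27ac promoter signal flanks the TSS
on both sides), distance ties broken by lexicographic gene id.
Concordance is the Spearman correlation of DEG and promoter-DA-peak
fold-changes over genes differential in both layers, with the exact
permutation p-value for ten or fewer tie-free pairs and the
t-approximation otherwise. The composite region ranking sums the
natural logs of a region's descending-count ranks (average ties) in
the two modalities; it depends on counts only through ranks and is
invariant to monotone transforms. RRHO grids use step
$s = \max(1, \lfloor N/100\rfloor)$, score each cell by the
hypergeometric tail of the top-list overlap (upper tail when overlap
exceeds expectation, lower tail with a depletion sign otherwise), and
apply no multiple-testing correction — the map is a display statistic.
Ranking scores are $-\log_{10}(p)\cdot\mathrm{sign}(\mathrm{lfc})$,
falling back to signed fold-changes where p is absent.

## The single-cell stage

The scRNA generator gives each of ~12 cell types a disjoint marker
block (8-fold elevated), draws per-cell depths Poisson-log-normal
around 2,000 counts (droplet-like sparsity at desk scale), assigns
cells to types by per-replicate Dirichlet-multinomial proportions, and
draws gene counts multinomially from the type profile. Planted effects
— a proportion shift, a module shift, a regulon-target shift, a
ligand shift — are each owned by disjoint gene pools so recovery
checks cannot confound them. Because profiles renormalize, raising 100
genes two-fold depresses the remaining genes by a few percent; this
compositional side-effect is real in droplet data too, and it is why
pseudo-bulk recovery is assessed on up-calls for an up-planted module.

Stage defaults: QC keeps cells with ≥ 500 detected genes and ≤ 20%
mitochondrial counts and genes detected in ≥ 3 cells (declared
substitutes for unpublished thresholds; per-cell QC statistics are
cached in the metadata, making the operation idempotent);
normalization is `log1p(1e4 * count/total)`. Typing correlates each
cell's marker profile with reference centroids (Spearman, minimum 0.2)
and flags cells whose label disagrees with the majority of their
k-means cluster on 20 principal components. Proportions are compared
by a two-sided Wilcoxon rank-sum across replicates, exact by
enumeration of the conditional distribution (ties included) up to
pooled size 12, normal approximation with tie correction beyond.
Pseudo-bulk units are replicate-wise *means* of normalized expression
(the averaged-profile convention), compared by Welch's t with BH per
type at $q < 0.2$ and a 0.1 pseudocount on unit means. Module scores
subtract the mean of seeded, expression-bin-matched control genes (25
bins, 100 controls per set gene). Regulon activity is the normalized
area under the recovery curve of regulon genes within the top 5% of a
cell's expression ranking (ties broken deterministically by gene id);
differential activity uses the rank-sum test with BH across regulons
within type at $q < 0.1$. Ligand–receptor edges weight an edge by the
product of ligand specificity in the sender and receptor specificity
in the receiver (means normalized across types, 0/0 → 0, so
specificities sum to one for every expressed gene), retain edges
detected in ≥ 10% of the relevant cells in at least one condition,
and rank by the condition delta. Regulon discovery is out of scope:
regulons and the ligand–receptor catalogue are inputs.

## Pipeline, determinism, and problem sizes

`run_pipeline()` drives simulate → bulk DE → ChIP DA → modules →
enrichment → integration → single cell from one YAML configuration
(`validate_config()` checks ranges and names every offending key),
writes each stage as TSV with 6-significant-digit formatting, and ends
with an atomically written manifest of MD5 checksums. All randomness
flows from per-call seeds derived from the configuration seed, so
identical configuration and seed give byte-identical outputs; stages
re-run alone resume from the previous run's files.

The packaged demo and the test suite run at deliberately modest sizes
— 2,000 genes, 27 regions, ~1,200-gene single-cell matrices with
100–150 cells per replicate, 10–50 simulation seeds per property —
chosen so the whole suite completes in a few minutes while leaving the
statistical conclusions stable across seeds.

## Known limitations

The generators do not emulate: read-level data (alignment and peak
calling are upstream of this package), batch effects beyond size
factors, the pooling of multiple animals into one replicate (a
variance component the replicate-level model absorbs silently),
gene–gene correlation beyond module structure, doublets or ambient
RNA, or fragment-level ChIP signal. Passing recovery tests on this
synthetic structure shows the statistics are implemented and calibrated
as specified; it does not certify performance on real data with those
additional artefacts. The differential engine is a fixed, fully
specified method — quasi-likelihood or exact NB tests, shrinkage
fold-change estimators and surrogate-variable correction are
intentionally out of scope.
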