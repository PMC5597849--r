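---
title: "Models and methods behind the mgwas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mgwas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, the tunable parameters
and their defaults, the numerical conventions, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

# The pipeline and its assumptions

The package analyses a case-control microbiome cohort through five
stages: gene profiling, marker discovery, metagenomic linkage group
(MLG) construction, phenotype association, and classification. The
underlying assumptions are those of reference-based shotgun
metagenomics: reads have been uniquely mapped to a non-redundant gene
catalogue upstream (mapping itself is out of scope), counts are
proportional to gene length times the carrying organism's abundance,
and gene annotations (genome hits with identity/coverage, KO
assignments) are consumed as tables.

## Gene relative abundance

For counts $r_{gs}$ and gene lengths $L_g$,
$$a_{gs} = \frac{r_{gs}/L_g}{\sum_{g'} r_{g's}/L_{g'}}.$$
The phrase "divide by gene length and by total mapped reads" admits a
literal reading $r_{gs}/(L_g R_s)$ whose columns do not sum to one; the
established MGWAS lineage sum-normalizes, and "relative abundance"
semantics require columns summing to 1, so the sum-normalized form is
the default and the literal variant is available via
`renormalize = FALSE`. All-zero samples are preserved (flagged) rather
than dropped, and excluded from diversity statistics.

## Taxonomic and functional aggregation

A gene is assigned at a rank from its single best DNA-identity hit
(ties broken by higher coverage, then lexicographic taxon id — multi-hit
handling is not specified by the method lineage, and single assignment
keeps profiles conservative). The hit must cover at least 70% of the
gene; identity thresholds are 95 / 85 / 65 % for species / genus /
phylum, inclusive at the boundary. Unassigned genes pool into
`unclassified`, so every aggregation conserves total abundance per
sample; the same holds for KO/module/pathway profiles with an
`unannotated` pool.

## Richness and diversity

Rarefied gene count subsamples a fixed number of reads *without
replacement* (multivariate hypergeometric) and averages the number of
detected genes over `draws` drawings (default 30, the conventional
value). The expected value has the closed form
$\sum_g [1 - \binom{N-r_g}{d}/\binom{N}{d}]$, which the tests use as an
independent oracle. The depth is a parameter: the 11-million-read depth
used on real cohorts is impractical for package-scale data, so the
pipeline defaults to the smallest sample total. The Shannon index uses
the natural log and is computed on the gene-level profile by default;
the level is a choice the method lineage leaves open, so it is exposed
as an argument.

# Marker discovery

## Stratification adjustment

Gene rows are standardized (centered, scaled by row sd; zero-sd rows
only centered); the top `k_axes` eigenvectors of the sample-by-sample
covariance of the standardized matrix are projected out of every gene
row. This is the abundance-profile analogue of EIGENSTRAT, with
covariance estimated from abundances instead of genotypes. `k_axes`
defaults to 2; the number of axes the original method removed is
unstated, and no scree rule is reliable at package scale, so the value
is an explicit parameter everywhere.

Two properties of this adjustment matter in practice and are visible in
the test suite:

* When a strong disease effect dominates the covariance (as in the
  synthetic power scenarios, where six of forty species carry four-fold
  shifts), the leading eigenvector *is* the disease axis, and removing
  it destroys the signal. Power scenarios therefore run with
  `k_axes = 0`; the adjustment is for cohorts where stratification, not
  the phenotype, dominates.
* Because the per-gene test is rank-based, linear residualization fully
  corrects only perturbations that are approximately linear on the
  tested scale. The confounder-removal tests plant a moderate axis
  (strength 0.3 on the log scale) for this reason; a much stronger
  log-scale axis leaves a rank-detectable nonlinear residue no linear
  method can remove.

## Testing and FDR

The per-gene test is a two-tailed Mann-Whitney U on the adjusted
profiles. The exact null distribution is enumerated when
$n_1 + n_2 \le 12$ with no ties (two-tailed p as twice the smaller tail,
capped at 1); otherwise the normal approximation with tie correction
and continuity correction is used, matching the standard reference
implementation, which the tests compare against. Complete ties give
p = 1. Genes whose adjusted row has zero variance are skipped and
counted, not tested. Benjamini-Hochberg q-values implement the step-up
definition directly; markers are genes with `q < 0.05` (strict).
Enrichment direction is reported from *unadjusted* group means:
adjusted residuals are not interpretable as abundances, and a direction
should be readable off the raw profiles.

# Metagenomic linkage groups

The originating literature defers the co-abundance clustering algorithm
to earlier work without specifying it; the package defines a
reproducible, oracle-checkable stand-in that preserves the
"co-abundance cluster around a dominant member" semantics:

1. Seed with the unclustered gene of highest mean abundance.
2. Gather unclustered genes with Spearman $\rho \ge$ `rho_min` (default
   0.7) to the seed.
3. Recompute the medoid (member maximizing summed within-cluster
   correlation; ties by gene id) and re-gather, to stability or 20
   iterations.
4. Accept if at least `min_size` (default 5) members; otherwise retire
   the seed.

The procedure is deterministic given the data, invariant to gene order,
and every accepted cluster satisfies its own membership criterion on
re-check. MLG abundance is the interquartile mean (25%-trimmed mean) of
member-gene abundances scaled by member count — a robust version of the
summed abundance that a single aberrant gene cannot move (the exact
robust estimator in the lineage is unstated). Taxonomy calls use the
gene-vote rules (species: $\ge$ 90% of genes at $\ge$ 95% DNA identity
and $\ge$ 70% coverage; genus: $\ge$ 80% at $\ge$ 85% DNA *and* protein
identity), inclusive at every boundary, with the supporting fraction
always reported. Direction requires Mann-Whitney `P < 0.05` (strict),
by group medians.

# Association statistics

* **Network.** All unordered MLG pairs with $|\rho| > 0.4$ (strict),
  Spearman over all pooled samples — pooling matches the stated
  practice of computing co-occurrence across both groups.
* **Gross abundance ratio.** Per sample,
  $\sum$ case-enriched / $\sum$ control-enriched MLG abundance; zero
  denominators yield missing values rather than infinities. Both
  Spearman (primary, consistent with the correlation panels) and
  Pearson are reported against glucose.
* **Spearman p-values** are exact by full permutation enumeration for
  $n \le 10$ (a C++ loop over $n!$ orderings; valid under ties because
  distinct orderings of tied ranks have equal multiplicity) and use the
  t approximation above.
* **PERMANOVA** uses Anderson's pseudo-F from among/within sums of
  squared Bray-Curtis distances and the permutation p-value
  $(1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$, permuting raw labels (no
  strata are reported in the lineage). The pseudo-F is checked against
  both an independent implementation and `vegan::adonis2`.
* **db-RDA** is delegated to `vegan::capscale` — the lineage itself
  used vegan — wrapped to return the constrained-axis sample scores,
  the percent variance of the first two axes, and feature loadings as
  correlations with the constrained scores. Negative eigenvalues of the
  embedding are discarded with a logged note.

# Classification

No random-forest package is assumed: the forest is implemented in the
package's own C++ (CART with Gini splits, bootstrap resampling,
`mtry = floor(sqrt(p))`, fully grown trees), with out-of-bag
probability scores and permutation importance (mean decrease in OOB
accuracy) — the importance definition the lineage reports. `n_trees`
defaults to 10 000 per the stated convention; desk-scale tests use
300-500, where the importance ranking is already stable in the test
scenarios.

The evaluation scheme the lineage leaves unspecified ("cross-validation
error") is fixed here as 5-fold stratified cross-validation repeated 10
times with pooled out-of-fold probability scores; AUC uses the rank
(Mann-Whitney) formulation with ties counted 0.5, and its 95% CI is a
stratified percentile bootstrap (default 10 000 replicates). The
feature ranking for the subset-size sweep is computed once on the full
data, as the lineage implies; this optimistically biases the curve, and
the report carries an explicit note to that effect.

# The synthetic world

The generator's defaults are chosen once as a realistic desk-scale
cohort and are not tuned to test outcomes:

| parameter | default | rationale |
|---|---|---|
| `n_case`, `n_control` | 40 / 40 | balanced power-analysis cohort; the cohort-shaped example uses 43 / 81 |
| `n_species`, `genes_per_species` | 40, 25 | 1000 genes: large enough for FDR behaviour, small enough for seconds-scale tests |
| `gene_length_range` | 500-1500 bp | typical prokaryotic gene lengths |
| `depth_mean`, `depth_cv` | 2×10^5, 0.2 | mean counts ~100/gene (detection without saturation); log-normal depth makes rarefaction non-trivial |
| `n_diff_species`, `effect_log2fc` | 6, 2 | a handful of four-fold shifted species, alternating directions |
| `phenotype_noise_sd` | 0.4 mmol/L | glucose measurement + biological noise at the scale of the diagnostic cuts |
| `annotation_noise` | 0.05 | a small fraction of spurious catalogue hits |
| `overdispersion` | 0 (Poisson) | unique-read counting; a negative-binomial knob exists but is off |

Species abundances are log-normal (between-species sd 1.5, within 0.7
on the log scale); counts are Poisson around
depth × species relative abundance × the gene's length share within its
species, so per-sample totals track the depth and expected counts are
length-proportional within a species.

**The glucose model.** OGTT glucose at 0/60/120 min is an affine
function of the *standardized* true case/control species log-ratio with
intercepts near the diagnostic thresholds (4.7 / 7.8 / 6.6 mmol/L) plus
Gaussian noise, and the case label is the top-`n_case` quantile of
fasting glucose — a threshold diagnosis. The slope scales with
`effect_log2fc / 2` (times a `glucose_coupling` switch): when no
differential effect is planted, the phenotype carries no microbiome
signal and labels are exchangeable. The alternative — a fixed slope —
would make labels correlate with whichever species happen to drive the
ratio even under a null effect, so "no planted effect" would not be a
null world. A consequence worth knowing: with the default noise, the
labels agree with the planted case set at roughly 80-90%, so label
noise is part of the stated world and caps recoverable classification
performance; `bayes_auc()` computes that ceiling by Monte-Carlo from
the generative model itself.

**The confounder.** The stratification axis is
$(\text{N}(0,1) + \text{case indicator contrast})/\sqrt{2}$ — aligned
with case status, because an axis independent of the labels would
inflate nothing and there would be nothing for the adjustment to fix.
`confounder_strength` scales its loading on a random half of species on
the log scale.

**What the generator does not emulate** — and hence what a green test
does not establish: real taxonomies and databases (taxon labels are
synthetic), zero-inflation and strain-level variation, compositional
effects of a few dominating taxa, read-level artifacts (chimeras,
mapping bias), longitudinal structure, or diet/lifestyle covariates.
Recovery results say the algorithms work on data matching their model,
not that the biological conclusions of any particular cohort transfer.

# Numerical conventions and degenerate inputs

All ranks are average ranks. Ties in orderings (seeds, medoids, taxon
votes, importance) break lexicographically, making every stage
deterministic given data and seed. Every stage seed is derived from one
master seed by a pure hash (`derive_seed`), kept below $2^{31}$.
Degenerate inputs have defined behaviour: all-zero samples are flagged
and kept (profiles) or NA (diversity, ratios); constant features are
skipped with warnings (tests, correlations, networks); empty member
lists, single-class labels, and impossible thresholds raise errors
naming the offending input; the pipeline aborts with the failing stage
name.

# Known limitations

* The co-abundance clustering is a stand-in for an unspecified
  algorithm; on real data the MLG partition (though not its qualitative
  behaviour) will differ from canonical implementations.
* Linear eigenvector adjustment cannot fully de-confound rank tests
  against strongly nonlinear (log-scale) axes, and removes true signal
  when the disease effect dominates covariance — both are properties of
  the method class, surfaced honestly by the tests.
* The null-calibration KS check runs on a one-gene-per-species world:
  within-species gene blocks make per-gene p-values dependent, which
  invalidates the iid assumption of the KS test without invalidating
  per-gene calibration.
* PERMANOVA permutes raw labels; no repeated-measures or strata support.
* The classifier evaluation reuses a full-data importance ranking for
  the subset sweep (flagged optimism); nested ranking would be slower
  but unbiased.
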