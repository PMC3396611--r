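---
title: "Methods: genome-wide survival screening of FFPE RNA-seq counts"
author: "ffpescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide survival screening of FFPE RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpescreen)
```

# The problem

Archival formalin-fixed paraffin-embedded (FFPE) tumor blocks with mature
clinical follow-up are the most abundant source of outcome-annotated tissue,
and RNA-seq of FFPE RNA makes transcriptome-wide biomarker screening in such
cohorts possible. The statistical task is: given a raw count matrix over
~20,000 features for ~100–150 patients, time-to-recurrence follow-up with
few events, and a gene annotation, decide which RNAs — annotated, intronic,
or previously unannotated intergenic — associate with recurrence risk, while
controlling the false discovery rate and reporting honest effect sizes.

`ffpescreen` implements that pipeline end to end: normalization, a
feature-vectorized univariate Cox screen with robust variance, Storey
q-values, TDRDA effect-size sets, regression-to-the-mean (RTM) corrected
standardized hazard ratios, a read-island algorithm for discovering
transcribed intergenic regions, thresholded co-expression networks, ER
status calling, and cross-platform concordance statistics — plus a
synthetic-cohort generator so every stage can be exercised and tested
without any external data.

# Normalization

Raw counts are transformed as `log2(count)` with the special case
`log2(0) := 0`. This convention deliberately collides counts 0 and 1 at
the value 0; we keep it as defined rather than patching it with
pseudocounts, because the downstream statistics are specified on exactly
this scale. Features whose maximum count over all samples is below 5 are
excluded before anything else (`max_count_filter()`); the third quartile
is computed after this exclusion (configurable in principle by filtering
or not before calling the normalizer).

Third-quartile normalization (`third_quartile_normalize()`) shifts every
sample's log2 values by (cohort mean Q3 − sample Q3), where Q3 is the
per-sample third quartile of a *reference feature class*: annotated
(RefSeq-class) features serve as the reference for annotated and
intergenic matrices, intronic features for intronic matrices. Two
numerical choices are deliberate:

* **Quantile definition.** Linear interpolation between order statistics
  (R's type 7), the most common convention; exposed via `type`.
* **Zeros included.** Q3 is computed over all reference features,
  including zero counts; no exclusion is applied.

After normalization each sample's reference Q3 equals the cohort mean Q3
exactly (to machine precision) — this identity is asserted in the tests.
One caveat worth stating: the transformation is *not* location-equivariant
sample by sample. Adding a constant c to one sample's log2 values moves
the cohort mean Q3 by c/n, so every normalized sample (including the
altered one) moves by exactly c/n; between-sample contrasts are untouched,
which is what the survival screen consumes.

The relative log expression diagnostic (`rle_diagnostic()`) reports, per
feature and sample, the log2 value minus the within-patient median, with
per-sample median and IQR summaries; tightly distributed RLE values
centered on zero indicate the shifts did their job.

# The survival screen

For each feature, expression is standardized to z-scores (n−1
denominator) and fitted in a univariate Cox proportional-hazards model, so
`exp(beta)` is the standardized hazard ratio (SHR): the proportional
change in recurrence hazard per 1-SD increase in normalized expression.

**Implementation.** The one-covariate Newton–Raphson iteration is
vectorized across features: each iteration evaluates risk-set sums for
all features simultaneously with matrix cumulative sums, so a
20,000-feature screen takes seconds rather than minutes. Ties use the
Efron approximation by default (Breslow selectable); convergence is to a
relative tolerance of 1e−9 with at most 100 iterations, step-damped at
±2. Estimates, model-based SEs, and robust SEs are validated in the test
suite against `survival::coxph(robust = TRUE)` to 1e−7, and against
direct maximization of the explicit partial likelihood on small
instances.

**Robust variance.** The Lin–Wei sandwich estimator
I⁻¹ (Σᵢ Uᵢ²) I⁻¹, with Uᵢ the per-subject score residuals, guards
against departures from the Cox model (nonlinearity, non-proportional
hazards). With few events, however, the sandwich estimate can dip
*below* the model-based SE by chance, which inflates the extreme tail of
the null z distribution — measured on pure-null synthetic cohorts with
26 events, robust-SE Wald p-values near 1e−4 were ~3× too frequent while
model-based p-values were calibrated. Since the sandwich exists to
protect against variance *inflation*, the default Wald inference uses
`max(robust SE, model SE)`; `inference_se = "robust"` restores the
literal rule. The robust SE itself is always computed and reported.

**FDR.** Storey q-values with tuning parameter λ = 0.5:
π₀ = #{p > λ} / ((1 − λ) m), clipped to (0, 1], followed by the usual
step-up monotone enforcement. On pure-null cohorts the empirical FDR of
the q < 0.10 rule is verified to stay at or below its nominal level (the
acceptance suite runs 200 replicate null cohorts of 136 patients × 2,000
features).

**TDRDA sets.** For each candidate lower bound B ≥ 1 (grid 1.00–2.00 in
steps of 0.05, covering the range of corrected SHRs such cohorts
produce), the screen tests H0: |β| ≤ log B with a shifted Wald test and
computes per-bound Storey q-values; a feature's reported TDRDA value is
the largest B whose set contains it at FDR 10%. Two design points:

* The default p-value is `min(1, 2(1 − Φ((|β| − log B)/se)))`. The
  factor 2 accounts for the two screening directions, and makes the
  B = 1 set coincide *exactly* with the ordinary two-sided screen at the
  same FDR — the property that anchors the procedure. A per-direction
  variant (two separate one-sided screens, Crager-style) is available
  via `directional = TRUE`.
* Set nestedness (membership at B implies membership at every smaller
  bound) is enforced along the grid, so the reported maximum bound is
  well defined even though per-bound π₀ estimates fluctuate.

**RTM correction.** Genome-wide screening selects extreme estimates, so
the largest observed SHRs overstate their true effects. The correction
is empirical-Bayes normal–normal shrinkage: τ² = max(0, Var(β̂) −
mean(se²)), and each estimate is pulled toward the cross-feature mean
with weight τ²/(τ² + seᵢ²). The exact form of the published correction
is not reproducible from its citation alone; this is the canonical
structure with the right limits (no shrinkage as se → 0, full shrinkage
when between-feature variance is explained by noise), and it is
validated by the property that matters — corrected estimates have lower
mean squared error against the simulation truth than raw ones.

# Intergenic transcript discovery

Pooled uniquely-mapped reads from all patients are processed as:

1. **Islands** (`build_islands()`): maximal intervals of strictly
   overlapping reads. Coordinates are 0-based half-open throughout
   (BED/refFlat convention), so reads that merely abut — one ends where
   the next starts — belong to different islands.
2. **Merge cutoff** (`estimate_merge_cutoff()`): candidate merge
   distances are scored by the base-level Jaccard index between the
   merged-region union and the union of annotated gene bodies
   ([txStart, txEnd) spans). Too small a cutoff leaves intragenic gaps
   uncovered; too large a cutoff bleeds regions into intergenic space;
   the overlap objective peaks in between, and ties go to the smallest
   candidate. A Bernoulli likelihood-ratio objective (region-level
   ≥50% gene overlap versus the genome-wide gene-body fraction) is
   selectable; we did not make it the default because with a fixed null
   success probability the log-likelihood is monotone in the region
   count and degenerates into rewarding either no merging or unlimited
   merging regardless of gene overlap.
3. **Merging** (`merge_islands()`): gap semantics differ by stage, and
   both are explicit. Cutoff scanning uses tolerance semantics
   (gap ≤ d); the final condensation of significant regions uses the
   strict printed rule (gap < 1000 bp: a 999 bp gap merges, 1000 does
   not). `merge_islands(cutoff = 0)` is the identity.
4. **Retention filters** (`filter_rois()`): average read count ≥ 5
   across the patient population, length ≥ 100 bp, and read depth
   (average count / length) ≥ 0.075 — all inclusive thresholds.
5. **Intergenic classification** (`classify_intergenic()`): a region is
   intergenic iff it shares zero bases with any annotated transcript
   span, either strand (a region inside an intron is *not* intergenic).
   Strand is ignored because the classification is against transcript
   spans, not exons.
6. **Counting and condensation**: reads overlapping each region are
   counted per patient (`roi_counts_per_patient()`), feeding the same
   normalization and screen as annotated features;
   `post_fdr_merge()` condenses nearby significant regions and reports
   within-group versus between-region co-expression, the evidence that
   merged fragments are pieces of one transcript.

Island building and merging are validated against brute-force oracles
(connected components of the explicit overlap graph; O(n²)
transitive-closure merging), and the whole chain is validated by
rediscovery: on synthetic genomes, ≥90% of hidden transcribed intergenic
loci that pass the filters by construction are recovered as intergenic
regions with ≥50% reciprocal overlap.

# Networks, ER status, concordance

**Co-expression graphs** (`correlation_graph()`): all-pairs Pearson
correlation on normalized log2 values; an edge wherever R strictly
exceeds the threshold (default 0.6), positive correlations only by
default (an |R| mode exists); nodes with no edge are dropped. Where the
convention is stated both as R > 0.6 and R ≥ 0.6 in different places,
we chose the strict inequality; at a threshold crossed by continuous
correlations the boundary case has probability zero, but the choice is
documented and the boundary behavior tested. Components and degrees come
from igraph.

**ER calling** (`call_er_status()`): "cutoffs set by visual inspection"
is replaced by a reproducible default — a two-component Gaussian mixture
fitted by EM with deterministic initialization (means at the 25th/75th
percentiles, equal variances, equal weights), cutoff at the midpoint of
the component means; explicit cutoffs override the fit, and degenerate
(unimodal or collapsed) fits produce an instructive error rather than a
call. Status is positive iff ESR1 ≥ cutoff; PGR is used only for a
discordance flag (PGR+/ER− and PGR−/ER+ tumors are biologically rare).

**Concordance** (`lin_ccc()`, `ct_normalize()`,
`prognostic_agreement()`, `hazard_ratio_scatter_stats()`): Lin's
concordance correlation coefficient uses population (n-denominator)
moments, Lin's original definition; both vectors constant is an error.
RT-PCR crossing thresholds are normalized as cohort median C_T minus
C_T, so higher is more expressed. Cross-platform prognostic agreement
classifies features as prognostic at p < 0.05 per platform (the
conventional default, configurable), tabulates the 2×2 agreement, and
tests it with Fisher's exact test, optionally stratified by abundance
bin. Hazard-ratio scatter statistics are computed on the log2-HR scale.

# The synthetic cohort generator

`simulate_cohort()` draws, under one mandatory seed:

* **Abundance composition**: features are assigned to median-count bins
  (<10, 10–99, 100–999, ≥1000) with proportions matching the published
  cohort's composition (5817 : 6245 : 7657 : 743 of 20,462); a
  feature's target median is log-uniform within its bin, with the lowest
  bin reaching below a median of 1 so the cohort carries the
  sub-threshold tail the max-count exclusion exists to remove.
* **Biological structure**: latent Gaussian log2 expression with SD 1.5
  per feature (tumor cohorts spread key genes over orders of magnitude),
  with co-expressed blocks sharing a latent factor at correlation
  `block_rho` (default blocks of 51, 14, 12, 10, 5 features at ρ = 0.7,
  echoing observed network sizes).
* **Counts**: negative-binomial around 2^latent scaled by lognormal
  library-size factors (CV 0.3), dispersion α = 0.3 (variance
  μ + αμ²), FFPE-realistic.
* **Survival**: exponential (constant baseline hazard, the simplest
  model satisfying proportional hazards, so Cox recovery is
  well-defined) with log hazard equal to the sum of effect ×
  standardized latent expression over prognostic features.
  Administrative censoring at a single cutoff calibrated numerically so
  the expected event count hits the target (26 of 136 by default);
  `censor_rate` is honored when no event target is given. The
  censoring-time distribution of the real cohort is unpublished, so a
  single administrative cutoff is the one-parameter choice.
* **Effects**: a small fraction of features (default 0.001) get
  independent N(0, 0.3) per-SD log-hazard effects, drawn *outside* the
  blocks so every other feature is exactly null. The default fraction is
  deliberately small: the hazard is a sum over prognostic features, and
  thousands of independent effects would give the cohort an absurdly
  dispersed prognostic index. Realistic strong-signal cohorts are
  emulated instead with *module-level* effects (`block_effects` or
  `block_hazard_sd`): a block factor with effect γ makes each member's
  marginal per-SD log hazard γ√ρ, which the truth table records. The
  analysis scripts use two strong modules (a poor-prognosis
  proliferation-like block, a protective ER-like block) over a null
  background — few underlying prognostic dimensions with many features
  loaded on them, which is how real expression cohorts produce thousands
  of marginal associations from limited events.

`simulate_intron_counts()` adds an intronic counterpart per feature with
~3-fold abundance and a latent correlation of 0.85, calibrated so the
observed count-scale intron–exon correlation lands near the ~0.67 median
real cohorts show after count-noise attenuation.
`simulate_two_platform()` re-measures true log HRs with independent
noise for concordance exercises. `simulate_screen_instance()` generates
Gaussian expression with survival driven by a single feature — the
estimator-validation layer, free of count noise and of the
non-collapsibility that makes marginal Cox coefficients differ from
their generating values when many features drive the hazard at once.

The synthetic genome (`synthetic_genome()`, `simulate_read_islands()`)
places non-overlapping multi-exon genes, isolated intergenic loci, and
fragmented locus pairs (two co-expressed intervals 200–700 bp apart, the
case the <1000 bp condensation repairs), then draws 50 bp reads (one
round number for post-trimming usable read length) with Poisson counts
per unit, lognormal per-patient depths, and shared per-transcription-unit
expression factors.

**What the generator does not emulate**: FFPE degradation chemistry and
its 3'/5' coverage biases, barcode demultiplexing, mapping artifacts,
strand errors, GC or length biases, non-proportional hazards, and
informative censoring. Passing tests therefore certify the statistical
machinery under the model's assumptions, not robustness to every
artifact of real FFPE libraries.

# Problem sizes used in the tests and acceptance runs

The default test and acceptance runs use desk-scale versions of the
study conditions: null-FDR calibration on 200 replicate cohorts of 136
patients × 2,000 features; estimator recovery on 200 instances of 500
subjects × 50 features; oracle equivalence on 100 random 10-kb read
fixtures and ≤8-subject Cox instances; end-to-end rediscovery on three
synthetic genomes. The full-scale analysis under `analysis/` runs the
complete 20,462 × 136 screen (seconds, thanks to the vectorized fits).
The headline discovery counts of the motivating cohort depend on its
deposited patient data and are not reproducible from synthetic data;
what is reproducible — the filter arithmetic, the bin-table
percentages, FDR control, estimator recovery, the normalization
identity, and intergenic rediscovery — is what the acceptance script
recomputes.

# Known limitations

* The RTM correction and the TDRDA membership rule are principled
  reconstructions of published procedures whose exact formulas are not
  in the primary text; both are documented above and validated by their
  defining properties rather than against printed per-gene values.
* The merge-cutoff objective is a surrogate for an unpublished
  likelihood; the Jaccard default is reproducible and monotone but not
  unique.
* Marginal truth values for block members (γ√ρ) are first-order
  approximations; with very strong modules, non-collapsibility makes
  realized marginal coefficients deviate from them.
* The screen is univariate by design; no multivariable or penalized
  models are provided.
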