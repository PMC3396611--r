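# ffpescreen

Genome-wide survival screening of RNA-seq counts from archival tumor
tissue.

Hospital pathology archives hold large numbers of formalin-fixed
paraffin-embedded (FFPE) tumor blocks with mature clinical follow-up, and
RNA-seq of FFPE RNA makes them usable for transcriptome-wide biomarker
discovery. `ffpescreen` is an R implementation of the statistical pipeline
for that setting — a cohort of ~136 breast-cancer patients with ~26
recurrence events and raw counts for ~20,000 RNAs is the scale it is built
around — together with a synthetic-cohort generator that reproduces the
statistical structure the analysis assumes, so the whole pipeline runs,
and is tested, entirely offline.

## What it computes

For each feature (annotated transcript, intronic RNA, or discovered
intergenic region), expression is `log2(count)` with `log2(0) := 0`,
third-quartile normalized: each sample is shifted so its Q3 of
reference-class log2 counts equals the cohort mean Q3. The screen then
fits, per feature, the univariate Cox proportional-hazards model on
standardized expression z:

    h(t | z) = h0(t) · exp(β z)

so `exp(β)` is the standardized hazard ratio (SHR) — the proportional
change in recurrence hazard per 1-SD increase in expression. Inference
uses the Lin–Wei robust sandwich variance (floored at the model-based SE
for calibrated tails at few events); false discovery rates are Storey
q-values with λ = 0.5; TDRDA sets report, per identified feature, the
largest lower bound B such that |SHR| > B can be claimed at FDR 10%;
and empirical-Bayes shrinkage corrects the selection-inflated effect
sizes for regression to the mean.

Around the screen sit: the read-island algorithm for discovering
transcribed intergenic regions (islands → maximum-overlap merge cutoff →
average-count ≥ 5, length ≥ 100 bp, depth ≥ 0.075 filters → refFlat
subtraction → per-patient counting → <1000 bp condensation of significant
regions), co-expression networks thresholded at R > 0.6, ER status calls
from bimodal ESR1/PGR expression, and cross-platform concordance (Lin's
CCC, Pearson r on log2 hazard ratios, exact 2×2 prognostic-agreement
tests). Details and design rationale are in
`vignettes/ffpe-survival-screening.Rmd`.

## Worked example

```r
library(ffpescreen)

cfg <- cohort_config(
  n_patients = 136, n_features = 3000, n_events_target = 26,
  block_sizes = c(60, 30), block_effects = c(1.3, -0.8), seed = 2012
)
cohort <- simulate_cohort(cfg)
#> Synthetic cohort: 3000 features x 136 patients; 25 events

keep <- max_count_filter(cohort$counts, threshold = 5)$keep
norm <- third_quartile_normalize(log2_transform(cohort$counts[keep, ]))
#> Third-quartile normalized matrix: 2992 features x 136 samples
#>   reference class: refseq  cohort mean Q3: 7.84

screen <- survival_screen(norm, cohort$survival, fdr = 0.10, lambda = 0.5)
hits <- subset(screen, q < 0.10)
#> 39 features identified at FDR < 10%
head(hits[order(hits$p), ], 5)
#>    feature_id      shr robust_se            p            q tdrda_lower_bound  shr_rtm
#> 23    FT00023 2.787321 0.1706361 9.120884e-09 0.0000272532               1.3 1.236193
#> 37    FT00037 3.210811 0.1818639 1.239415e-07 0.0001851686               1.3 1.187756
#> 35    FT00035 3.101228 0.1837362 2.689922e-07 0.0002679162               1.3 1.182914
#> 46    FT00046 2.901179 0.2200337 1.365490e-06 0.0008735502               1.2 1.171339
#> 58    FT00058 2.498049 0.1900821 1.461764e-06 0.0008735502               1.2 1.188856
```

The cohort plants two prognostic co-expression modules (a poor-prognosis
block with factor effect +1.3, a protective block at −0.8) on a null
background. With 25 events the screen identifies 39 features; the top
hits are block members with raw SHRs near 2.8–3.2 per SD, TDRDA lower
bounds of 1.2–1.3 (the largest |SHR| magnitude each can be claimed to
exceed at FDR 10%), and RTM-corrected SHRs of ~1.17–1.24 — the
shrinkage quantifying how much of the raw effect is selection inflation
at this event count.

## The full analysis

Numbered drivers under `analysis/` run the complete workflow at study
scale (20,462 features × 136 patients) and write their tables under
`results/`:

    Rscript analysis/01_simulate.R               # cohort + genome + reads
    Rscript analysis/02_normalize.R              # filter, Q3-normalize, RLE
    Rscript analysis/03_screen.R                 # Cox screen, q/TDRDA/RTM, bin table
    Rscript analysis/04_discover_intergenic.R    # islands -> ROIs -> intergenic
    Rscript analysis/05_network_er_concordance.R # networks, ER calls, concordance
    Rscript analysis/06_report.R                 # JSON summary

`run_pipeline()` wraps the same stages behind a single config for
programmatic use.

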