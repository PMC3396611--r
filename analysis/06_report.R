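#!/usr/bin/env Rscript

# Stage 6: collect the run's headline numbers into one JSON report.

suppressMessages(library(ffpescreen))

scr <- read.delim("results/screen.tsv")
iscr <- read.delim("results/screen_introns.tsv")
tab <- read.delim("results/abundance_bins.tsv")
truth <- read.delim("results/data/truth.tsv")
surv <- read_survival("results/data/survival.csv")
inter <- read_bed("results/intergenic_rois.bed")

report <- list(
  n_patients = nrow(surv),
  n_events = sum(surv$event),
  n_features_screened = nrow(scr),
  n_identified_fdr10 = sum(scr$q < 0.10),
  n_intron_identified_fdr10 = sum(iscr$q < 0.10),
  max_tdrda_lower_bound = if (any(!is.na(scr$tdrda_lower_bound)))
    max(scr$tdrda_lower_bound, na.rm = TRUE) else NA,
  shr_range = range(scr$shr),
  shr_rtm_range = range(scr$shr_rtm),
  n_intergenic_rois = nrow(inter),
  abundance_bins = tab
)
jsonlite::write_json(report, "results/report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("report written to results/report.json\n")
str(report, max.level = 1)
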