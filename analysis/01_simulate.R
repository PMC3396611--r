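#!/usr/bin/env Rscript

# Stage 1: synthesize the study cohort.
#
# Generates a 136-patient cohort with ~20k features whose abundance
# composition follows the published count-bin table, 26 expected recurrence
# events, five co-expressed feature blocks (the largest echoing the
# cell-cycle module) carrying block-level prognostic effects, and a handful
# of independent prognostic singletons. Also builds a small synthetic
# genome with hidden transcribed intergenic loci and pools 50 bp reads
# from 8 patients for the discovery stage.

suppressMessages(library(ffpescreen))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20120713L   # fixed study seed for the whole analysis

# two prognostic modules (a strong poor-prognosis proliferation-like block
# and a protective ER-like block), one weak module, four null modules
cfg <- cohort_config(
  seed = seed,
  block_sizes = c(300L, 150L, 51L, 14L, 12L, 10L, 5L),
  block_effects = c(1.4, -0.8, 0.6, 0, 0, 0, 0),
  prognostic_fraction = 5e-4
)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out)

cat(sprintf("cohort: %d features x %d patients, %d events (censor cutoff %.1f months)\n",
            nrow(cohort$counts), ncol(cohort$counts),
            sum(cohort$survival$event), cohort$censor_time))
cat(sprintf("truly prognostic features: %d singletons + %d block members\n",
            sum(cohort$truth$prognostic & cohort$truth$block == 0),
            sum(cohort$truth$prognostic & cohort$truth$block > 0)))

introns <- simulate_intron_counts(cohort)
write_count_matrix(introns, file.path(out, "intron_counts.tsv"))
cat(sprintf("intronic counterpart matrix: %d features (abundance ~3x)\n",
            nrow(introns)))

genome <- synthetic_genome(seed = seed + 1L)
write_refflat(genome$genes, file.path(out, "refFlat.txt"))
write_bed(genome$loci, file.path(out, "hidden_loci.bed"))
reads <- simulate_read_islands(genome, n_patients = 8L, depth_scale = 1,
                               seed = seed + 2L)
write_bed(transform(reads, name = patient), file.path(out, "reads.bed"))
cat(sprintf("synthetic genome: %d genes, %d hidden intergenic loci, %d pooled reads\n",
            nrow(genome$genes), nrow(genome$loci), nrow(reads)))
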