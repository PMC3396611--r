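#!/usr/bin/env Rscript

# Stage 2: feature exclusion and third-quartile normalization.
#
# Features never reaching 5 counts in any patient are excluded; log2 counts
# (log2 of 0 set to 0) are then shifted per sample so that each sample's
# third quartile of reference-class log2 counts equals the cohort mean.
# The RLE diagnostic (per-feature log2 value minus the within-patient
# median) confirms the shifts center every sample on the cohort.

suppressMessages(library(ffpescreen))

counts <- read_count_matrix("results/data/counts.tsv")
filt <- max_count_filter(counts, threshold = 5)
cat(sprintf("max-count filter: %d of %d features retained (%d removed)\n",
            length(filt$retained), nrow(counts), filt$n_removed))
counts <- counts[filt$keep, , drop = FALSE]

norm <- third_quartile_normalize(log2_transform(counts))
print(norm)
write_count_matrix(round(norm$values, 4), "results/normalized.tsv")

rle <- rle_diagnostic(norm)
write.table(rle$summary, "results/rle_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("RLE medians in [%.3f, %.3f]; IQR median %.2f\n",
            min(rle$summary$median), max(rle$summary$median),
            median(rle$summary$iqr)))

# intronic matrix is normalized against its own feature class
introns <- read_count_matrix("results/data/intron_counts.tsv")
ikeep <- max_count_filter(introns, threshold = 5)$keep
inorm <- third_quartile_normalize(log2_transform(introns[ikeep, ]),
                                  reference_class = "intron")
write_count_matrix(round(inorm$values, 4), "results/normalized_introns.tsv")
cat(sprintf("intron matrix: %d features normalized against the intron class\n",
            nrow(inorm$values)))
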