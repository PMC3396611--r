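#!/usr/bin/env Rscript

# Stage 4: intergenic transcript discovery from pooled reads.
#
# Pooled uniquely-mapped reads are clustered into islands (strict overlap),
# islands are merged at a cutoff chosen to maximize overlap with annotated
# genes, merged regions pass three retention filters (average count >= 5,
# length >= 100 bp, depth >= 0.075), and regions overlapping no annotated
# transcript span are classified intergenic. Region counts per patient are
# then screened against survival like any other feature class, and
# significant regions separated by < 1000 bp are condensed into putative
# transcripts.

suppressMessages(library(ffpescreen))

reads <- read_bed("results/data/reads.bed")
names(reads)[4] <- "patient"
genes <- read_refflat("results/data/refFlat.txt")
n_pat <- length(unique(reads$patient))

disc <- discover_intergenic(reads, genes, n_patients = n_pat,
                            candidates = c(0, 10, 20, 30, 50, 100))
cat(sprintf("islands: %d; merge cutoff chosen: %d bp\n",
            nrow(disc$islands), disc$cutoff))
print(disc$scores, row.names = FALSE)
cat(sprintf("ROIs after filters: %d; classified intergenic: %d\n",
            nrow(disc$rois), nrow(disc$intergenic)))
write_bed(transform(disc$intergenic,
                    name = sprintf("ROI%04d", seq_len(nrow(disc$intergenic))),
                    score = count),
          "results/intergenic_rois.bed")

# recovery against the hidden loci the genome actually transcribes
hidden <- read_bed("results/data/hidden_loci.bed")
hit <- vapply(seq_len(nrow(hidden)), function(i) {
  l <- hidden[i, ]
  cand <- disc$intergenic[disc$intergenic$chrom == l$chrom, ]
  if (nrow(cand) == 0L) return(FALSE)
  ov <- pmax(0, pmin(cand$end, l$end) - pmax(cand$start, l$start))
  any(ov >= 0.5 * (l$end - l$start) & ov >= 0.5 * (cand$end - cand$start))
}, NA)
cat(sprintf("hidden loci recovered with >= 50%% reciprocal overlap: %d / %d\n",
            sum(hit), nrow(hidden)))

# per-patient region expression, written for any downstream screen
m <- roi_counts_per_patient(disc$intergenic, reads)
write_count_matrix(m, "results/intergenic_counts.tsv")

# condensation of nearby regions (the post-screen < 1000 bp merge applied
# here to all intergenic regions, with co-expression support)
inorm <- third_quartile_normalize(log2_transform(m),
                                  reference_class = "intergenic")
pm <- post_fdr_merge(disc$intergenic, gap = 1000, expr = inorm)
cat(sprintf("condensed %d regions into %d putative transcripts\n",
            nrow(disc$intergenic), nrow(pm$merged)))
cat(sprintf("median within-group co-expression R: %s; between: %s\n",
            format(pm$median_r_within, digits = 2),
            format(pm$median_r_between, digits = 2)))
write_bed(pm$merged, "results/intergenic_transcripts.bed")
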