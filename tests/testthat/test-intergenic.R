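test_that("island construction handles single and abutting reads", {
  one <- data.frame(chrom = "chr1", start = 100L, end = 150L)
  isl <- build_islands(one)
  expect_equal(isl$start, 100L)
  expect_equal(isl$end, 150L)
  expect_equal(isl$count, 1L)

  # half-open: (0,50) and (50,100) abut but do not overlap
  ab <- data.frame(chrom = "chr1", start = c(0L, 50L), end = c(50L, 100L))
  expect_equal(nrow(build_islands(ab)), 2L)

  ov <- data.frame(chrom = "chr1", start = c(0L, 49L), end = c(50L, 99L))
  expect_equal(nrow(build_islands(ov)), 1L)
  expect_equal(build_islands(ov)$count, 2L)
})

test_that("islands match a per-base coverage oracle on random reads", {
  set.seed(23)
  for (i in 1:10) {
    reads <- random_reads(1000, chrom_len = 10000L)
    isl <- build_islands(reads)
    oracle <- coverage_islands_oracle(reads)
    expect_equal(isl$start, oracle$start)
    expect_equal(isl$end, oracle$end)
    expect_equal(isl$count, oracle$count)
    # base-level conservation: islands cover exactly the read union
    expect_equal(sum(isl$end - isl$start),
                 ffpescreen:::interval_union_length(reads))
  }
})

test_that("island merging respects strict and inclusive gap semantics", {
  isl <- data.frame(chrom = "chr1", start = c(0L, 1049L, 2100L),
                    end = c(50L, 1100L, 2150L), count = c(1L, 2L, 3L))
  # gaps: 999 between 1&2, 1000 between 2&3
  m <- merge_islands(isl, cutoff = 1000)
  expect_equal(nrow(m), 2L)
  expect_equal(m$count[1], 3L)   # merged pair sums counts

  # cutoff 0 (strict) is the identity
  expect_equal(merge_islands(isl, 0), isl, ignore_attr = TRUE)
  # inclusive semantics merge at gap == cutoff
  expect_equal(nrow(merge_islands(isl, 999, inclusive = TRUE)), 2L)
  expect_equal(nrow(merge_islands(isl, 999, inclusive = FALSE)), 3L)
})

test_that("merging matches the O(n^2) transitive-closure oracle", {
  set.seed(31)
  for (i in 1:8) {
    isl <- random_islands(60)
    isl <- build_islands(transform(isl, patient = "P"))  # disjoint islands
    for (cutoff in c(0, 25, 150, 1000)) {
      fast <- merge_islands(isl, cutoff)
      slow <- transitive_merge_oracle(isl, cutoff)
      expect_equal(fast, slow)
    }
  }
})

test_that("ROI count is non-increasing in the merge cutoff", {
  set.seed(37)
  isl <- build_islands(random_reads(600, chrom_len = 30000L))
  n_rois <- vapply(c(0, 10, 50, 200, 1000), function(d)
    nrow(merge_islands(isl, d, inclusive = TRUE)), 0L)
  expect_true(all(diff(n_rois) <= 0))
})

test_that("merge cutoff estimation picks the gap scale of the gene tiling", {
  # genes tiled by islands with 10 bp internal gaps; isolated intergenic
  # singletons far away. cutoff 0 leaves intragenic gaps uncovered,
  # cutoff 50 bleeds into flanking singletons placed 40 bp from a gene.
  genes <- data.frame(
    gene_name = sprintf("G%d", 1:5), name = sprintf("NM_%d", 1:5),
    chrom = "chr1", strand = "+",
    tx_start = seq(0L, 40000L, by = 10000L),
    tx_end = seq(0L, 40000L, by = 10000L) + 1000L,
    cds_start = 0L, cds_end = 0L, exon_count = 1L,
    stringsAsFactors = FALSE
  )
  islands <- do.call(rbind, lapply(seq_len(5), function(i) {
    g0 <- genes$tx_start[i]
    starts <- g0 + seq(0L, 900L, by = 100L)
    data.frame(chrom = "chr1", start = starts, end = starts + 90L,
               count = 5L, stringsAsFactors = FALSE)
  }))
  singles <- data.frame(chrom = "chr1",
                        start = genes$tx_end + 40L,
                        end = genes$tx_end + 90L,
                        count = 1L, stringsAsFactors = FALSE)
  far <- data.frame(chrom = "chr1",
                    start = seq(50000L, 90000L, by = 5000L),
                    end = seq(50000L, 90000L, by = 5000L) + 50L,
                    count = 1L, stringsAsFactors = FALSE)
  isl <- rbind(islands, singles, far)
  est <- estimate_merge_cutoff(isl, genes, candidates = c(0, 10, 50),
                               chrom_sizes = c(chr1 = 100000L))
  expect_equal(est$cutoff, 10)

  # degenerate candidate list returns that candidate
  expect_equal(estimate_merge_cutoff(isl, genes, candidates = 0)$cutoff, 0)
  # deterministic scoring
  est2 <- estimate_merge_cutoff(isl, genes, candidates = c(0, 10, 50),
                                chrom_sizes = c(chr1 = 100000L))
  expect_equal(est$scores, est2$scores)
})

test_that("ROI retention filters apply the three inclusive thresholds", {
  n_pat <- 10L
  rois <- data.frame(
    chrom = "chr1",
    start = c(0L, 500L, 1000L, 2000L),
    end = c(100L, 599L, 1200L, 2300L),
    # avg counts: 7.5 (depth exactly 0.075), 10, 2, 40
    count = c(75L, 100L, 20L, 400L)
  )
  kept <- filter_rois(rois, n_pat)
  # boundary ROI (length 100, avg 7.5, depth 0.075) retained;
  # length-99 ROI and low-avg-count ROI removed
  expect_equal(kept$start, c(0L, 2000L))
  expect_equal(kept$depth, kept$avg_count / kept$length)

  # brute-force triple-predicate oracle on random ROIs
  set.seed(41)
  rr <- random_islands(200)
  rr$count <- rpois(200, 60)
  kept2 <- filter_rois(rr, 4L)
  brute <- rr[rr$count / 4 >= 5 & (rr$end - rr$start) >= 100 &
                (rr$count / 4) / (rr$end - rr$start) >= 0.075, ]
  expect_equal(kept2$start, brute$start)

  # retained count non-increasing in each threshold
  for (arg in list(list(min_avg_count = 10), list(min_length = 200),
                   list(min_depth = 0.15))) {
    tighter <- do.call(filter_rois, c(list(rr, 4L), arg))
    expect_lte(nrow(tighter), nrow(kept2))
  }
})

test_that("intergenic classification uses full transcript spans, half-open", {
  genes <- data.frame(gene_name = "G", name = "NM", chrom = "chr1",
                      strand = "+", tx_start = 1000L, tx_end = 5000L,
                      cds_start = 1000L, cds_end = 5000L, exon_count = 2L,
                      stringsAsFactors = FALSE)
  genes$exon_starts <- list(c(1000L, 4000L))
  genes$exon_ends <- list(c(2000L, 5000L))
  rois <- data.frame(
    chrom = "chr1",
    start = c(2500L, 4999L, 5000L, 8000L),
    end = c(2600L, 5100L, 5100L, 8100L),
    count = 10L
  )
  inter <- classify_intergenic(rois, genes)
  # intronic ROI overlaps the span -> not intergenic; 1 bp overlap at the
  # txEnd boundary -> not intergenic; start == txEnd -> intergenic
  expect_equal(inter$start, c(5000L, 8000L))

  # random fixture against brute-force interval intersection
  set.seed(47)
  rr <- random_islands(150, chrom_len = 20000L, chroms = "chr1")
  brute <- rr[!(rr$start < 5000L & rr$end > 1000L), ]
  expect_equal(classify_intergenic(rr, genes)$start, brute$start)
})

test_that("per-patient ROI counts conserve reads and handle empties", {
  rois <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                     end = c(500L, 1500L), count = 0L)
  reads <- data.frame(
    chrom = "chr1",
    start = c(10L, 450L, 1200L, 700L),
    end = c(60L, 500L, 1250L, 750L),
    patient = c("A", "B", "A", "A")
  )
  m <- roi_counts_per_patient(rois, reads)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["chr1:0-500", "A"], 1L)
  expect_equal(m["chr1:0-500", "B"], 1L)
  expect_equal(m["chr1:1000-1500", "A"], 1L)
  # the read at 700-750 overlaps no ROI and is not counted
  expect_equal(sum(m), 3L)

  empty <- roi_counts_per_patient(rois, reads[0, ], patients = c("A", "B"))
  expect_true(all(empty == 0L))

  # single patient: totals match a brute-force overlap scan
  set.seed(53)
  rr <- build_islands(random_reads(200))
  rr <- merge_islands(rr, 100)
  reads1 <- random_reads(500)
  reads1$patient <- "P1"
  m1 <- roi_counts_per_patient(rr, reads1)
  brute <- vapply(seq_len(nrow(rr)), function(i)
    sum(reads1$start < rr$end[i] & reads1$end > rr$start[i]), 0L)
  expect_equal(unname(m1[, 1]), brute)
})

test_that("post-FDR merging condenses adjacent regions below 1000 bp gaps", {
  rois <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                     start = c(0L, 1099L, 5000L, 0L),
                     end = c(100L, 1200L, 5100L, 80L),
                     count = c(5L, 6L, 7L, 8L))
  res <- post_fdr_merge(rois, gap = 1000)
  expect_equal(nrow(res$merged), 3L)            # gap 999 merges, 3800 not
  expect_equal(res$merged$count[1], 11L)
  expect_equal(res$groups, c(1L, 1L, 2L, 3L))

  # no pairs within the gap: identity
  iso <- data.frame(chrom = "chr1", start = c(0L, 9000L),
                    end = c(100L, 9100L), count = 1L)
  expect_equal(nrow(post_fdr_merge(iso, 1000)$merged), 2L)

  # order independence
  res2 <- post_fdr_merge(rois[c(3, 1, 4, 2), ], gap = 1000)
  expect_equal(res2$merged, res$merged)
})

test_that("merged co-expressed region pairs out-correlate distant ones", {
  set.seed(59)
  n <- 60
  base <- rnorm(n)
  expr <- rbind(
    "chr1:0-100" = base + rnorm(n, 0, 0.2),
    "chr1:300-400" = base + rnorm(n, 0, 0.2),
    "chr1:5000-5100" = rnorm(n),
    "chr1:9000-9100" = rnorm(n)
  )
  rois <- data.frame(chrom = "chr1",
                     start = c(0L, 300L, 5000L, 9000L),
                     end = c(100L, 400L, 5100L, 9100L),
                     count = 1L)
  res <- post_fdr_merge(rois, gap = 1000, expr = expr)
  expect_gt(res$median_r_within, res$median_r_between)
})

test_that("the full discovery pipeline recovers hidden intergenic loci", {
  genome <- synthetic_genome(seed = 71)
  reads <- simulate_read_islands(genome, n_patients = 8, depth_scale = 1,
                                 seed = 72)
  disc <- discover_intergenic(reads, genome$genes, n_patients = 8)
  hits <- vapply(seq_len(nrow(genome$loci)), function(i) {
    l <- genome$loci[i, ]
    cand <- disc$intergenic[disc$intergenic$chrom == l$chrom, ]
    if (nrow(cand) == 0L) return(FALSE)
    ov <- pmax(0, pmin(cand$end, l$end) - pmax(cand$start, l$start))
    any(ov >= 0.5 * (l$end - l$start) &
          ov >= 0.5 * (cand$end - cand$start))
  }, NA)
  expect_gte(mean(hits), 0.9)
  # and no ROI labelled intergenic overlaps a gene span
  expect_equal(nrow(classify_intergenic(disc$intergenic, genome$genes)),
               nrow(disc$intergenic))
})

test_that("zero depth or empty genomes behave as specified", {
  genome <- synthetic_genome(seed = 73)
  none <- simulate_read_islands(genome, n_patients = 4, depth_scale = 0,
                                seed = 74)
  expect_equal(nrow(none), 0L)
  reads <- simulate_read_islands(genome, n_patients = 4, depth_scale = 1,
                                 seed = 75)
  # reads never extend past chromosome ends
  for (ch in names(genome$chrom_sizes))
    expect_lte(max(reads$end[reads$chrom == ch]),
               genome$chrom_sizes[[ch]])
  empty <- genome
  empty$genes <- empty$genes[0, ]
  empty$loci <- empty$loci[0, ]
  expect_error(simulate_read_islands(empty, 4, 1, seed = 76), "empty")
})
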