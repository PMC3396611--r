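#' Cluster pooled reads into read islands
#'
#' A read island is a maximal genomic interval in which consecutive pooled
#' reads overlap. Coordinates are 0-based half-open, so reads that merely
#' abut (one ends where the next starts) belong to different islands. The
#' union of the islands equals the union of the reads, and each island
#' carries the number of pooled reads inside it.
#'
#' @param reads Data frame with chrom, start, end (0-based half-open), one
#'   row per pooled read; extra columns ignored.
#' @return Data frame of islands: chrom, start, end, count, ordered by
#'   (chrom, start).
#' @export
build_islands <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  ord <- order(reads$chrom, reads$start, reads$end)
  r <- reads[ord, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(r)), r$chrom), function(idx) {
    s <- r$start[idx]; e <- r$end[idx]
    run_end <- cummax(e)
    new_isl <- c(TRUE, s[-1L] >= run_end[-length(idx)])
    grp <- cumsum(new_isl)
    data.frame(chrom = r$chrom[idx][!duplicated(grp)],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max),
               count = as.integer(table(grp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby islands into regions of interest
#'
#' Islands on the same chromosome separated by a gap below the cutoff are
#' merged, their pooled read counts summed. The default comparison is
#' strict (`gap < cutoff`, so cutoff 0 merges nothing and a 1000 bp cutoff
#' merges gaps up to 999 bp); `inclusive = TRUE` uses `gap <= cutoff`,
#' the tolerance semantics applied when scanning candidate cutoffs.
#'
#' @param islands Data frame with chrom, start, end, count.
#' @param cutoff Merge distance in bp, >= 0.
#' @param inclusive Merge at `gap <= cutoff` instead of `gap < cutoff`.
#' @return Data frame chrom, start, end, count (merged regions).
#' @export
merge_islands <- function(islands, cutoff, inclusive = FALSE) {
  stopifnot(cutoff >= 0)
  if (nrow(islands) == 0L) return(islands)
  ord <- order(islands$chrom, islands$start, islands$end)
  x <- islands[ord, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(x)), x$chrom), function(idx) {
    s <- x$start[idx]; e <- x$end[idx]; cnt <- x$count[idx]
    run_end <- cummax(e)
    gap <- s[-1L] - run_end[-length(idx)]
    sep <- if (inclusive) gap > cutoff else gap >= cutoff
    grp <- cumsum(c(TRUE, sep))
    data.frame(chrom = x$chrom[idx][!duplicated(grp)],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max),
               count = as.integer(tapply(cnt, grp, sum)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# union length of a set of intervals (per chrom), and intersection length
# of two interval sets; both on 0-based half-open data frames
interval_union_length <- function(x) {
  if (nrow(x) == 0L) return(0)
  m <- merge_islands(transform(x, count = 0L), cutoff = 0)
  sum(m$end - m$start)
}

interval_intersection_length <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(0)
  gx <- GenomicRanges::reduce(as_granges(x))
  gy <- GenomicRanges::reduce(as_granges(y))
  sum(IRanges::width(GenomicRanges::intersect(gx, gy)))
}

as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Choose the island merge cutoff by maximizing overlap with known genes
#'
#' Scans candidate merge distances; for each, islands are merged (tolerance
#' semantics, `gap <= d`) and the resulting regions are scored against
#' annotated gene bodies (refFlat transcript spans). The default score is
#' the base-level Jaccard index between the merged-region union and the
#' gene-body union: too small a cutoff leaves intragenic gaps uncovered,
#' too large a cutoff bleeds regions into intergenic space, and the overlap
#' criterion peaks in between. A `"bernoulli"` alternative scores the
#' likelihood ratio of region-level gene membership (>= 50% of region
#' length in gene bodies) against the genome-wide gene-body fraction.
#'
#' @param islands Data frame of read islands.
#' @param genes refFlat records (data frame from [read_refflat()]).
#' @param candidates Candidate cutoffs in bp.
#' @param objective `"jaccard"` (default) or `"bernoulli"`.
#' @param chrom_sizes Named vector of chromosome sizes (needed for the
#'   Bernoulli null; defaults to the maximum observed coordinate).
#' @return List with `cutoff` (best candidate; ties go to the smallest),
#'   and `scores` (data frame of candidate, score).
#' @export
estimate_merge_cutoff <- function(islands, genes, candidates,
                                  objective = c("jaccard", "bernoulli"),
                                  chrom_sizes = NULL) {
  objective <- match.arg(objective)
  if (!length(candidates)) stop("no candidate cutoffs supplied")
  gene_iv <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                        end = genes$tx_end, stringsAsFactors = FALSE)
  gene_len <- interval_union_length(gene_iv)
  genome_len <- if (is.null(chrom_sizes)) {
    sum(tapply(pmax(islands$end, 0), islands$chrom, max)) +
      sum(tapply(gene_iv$end, gene_iv$chrom, max)[
        setdiff(unique(gene_iv$chrom), unique(islands$chrom))], na.rm = TRUE)
  } else sum(chrom_sizes)
  scores <- vapply(candidates, function(d) {
    merged <- merge_islands(islands, d, inclusive = TRUE)
    if (objective == "jaccard") {
      inter <- interval_intersection_length(merged, gene_iv)
      uni <- interval_union_length(merged) + gene_len - inter
      inter / uni
    } else {
      ov <- region_gene_overlap(merged, gene_iv)
      succ <- ov / (merged$end - merged$start) >= 0.5
      p0 <- min(max(gene_len / genome_len, 1e-9), 1 - 1e-9)
      ph <- min(max(mean(succ), 1e-9), 1 - 1e-9)
      sum(succ * log(ph / p0) + (!succ) * log((1 - ph) / (1 - p0)))
    }
  }, 0)
  best <- candidates[which.max(scores)]  # which.max takes the first maximum,
                                         # i.e. the smallest tied cutoff,
                                         # because candidates are scanned
                                         # in the order supplied
  list(cutoff = best,
       scores = data.frame(candidate = candidates, score = scores))
}

# per-region overlap (bp) with the union of gene intervals
region_gene_overlap <- function(regions, gene_iv) {
  if (nrow(regions) == 0L) return(numeric())
  gr <- as_granges(regions)
  gg <- GenomicRanges::reduce(as_granges(gene_iv))
  hits <- GenomicRanges::findOverlaps(gr, gg)
  ov <- numeric(nrow(regions))
  if (length(hits)) {
    w <- IRanges::width(GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], gg[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov[as.integer(names(agg))] <- agg
  }
  ov
}

#' Region-of-interest summary metrics
#'
#' Adds `avg_count` (pooled count / number of patients), `length`, and
#' `depth` (avg_count / length) to merged regions.
#'
#' @param rois Data frame chrom, start, end, count.
#' @param n_patients Number of patients pooled.
#' @return The input with avg_count, length, depth columns.
#' @export
roi_metrics <- function(rois, n_patients) {
  stopifnot(n_patients >= 1)
  rois$avg_count <- rois$count / n_patients
  rois$length <- rois$end - rois$start
  rois$depth <- rois$avg_count / rois$length
  rois
}

#' Retention filters for candidate regions of interest
#'
#' Retains a region iff average read count >= `min_avg_count`, length >=
#' `min_length` bp, and read depth (average count / length) >=
#' `min_depth`; all thresholds inclusive.
#'
#' @param rois Data frame with chrom, start, end, count.
#' @param n_patients Number of patients in the pooled read set.
#' @param min_avg_count,min_length,min_depth Retention thresholds
#'   (defaults 5, 100 bp, 0.075).
#' @return Retained regions with metric columns attached.
#' @export
filter_rois <- function(rois, n_patients, min_avg_count = 5,
                        min_length = 100, min_depth = 0.075) {
  r <- roi_metrics(rois, n_patients)
  keep <- r$avg_count >= min_avg_count &
    r$length >= min_length &
    r$depth >= min_depth
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify regions as intergenic against a gene annotation
#'
#' A region is intergenic iff it shares no bases with any annotated
#' transcript span \[txStart, txEnd), either strand; a region inside an
#' intron therefore is not intergenic.
#'
#' @param rois Data frame of regions.
#' @param genes refFlat records.
#' @return The subset of `rois` with zero transcript overlap.
#' @export
classify_intergenic <- function(rois, genes) {
  if (nrow(rois) == 0L) return(rois)
  gene_iv <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                        end = genes$tx_end, stringsAsFactors = FALSE)
  hit <- IRanges::overlapsAny(as_granges(rois), as_granges(gene_iv))
  out <- rois[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count reads per region and patient
#'
#' Counts, for every region and every patient, the reads overlapping the
#' region by at least one base; each read contributes at most once per
#' region. The result is an intergenic-class count matrix that feeds the
#' same normalization and screening used for annotated features.
#'
#' @param rois Data frame of regions (rows become matrix rows, named
#'   `chrom:start-end`).
#' @param reads Data frame with chrom, start, end, patient.
#' @param patients Optional patient universe (columns); defaults to the
#'   patients present in `reads`.
#' @return Integer matrix, regions x patients.
#' @export
roi_counts_per_patient <- function(rois, reads, patients = NULL) {
  if (is.null(patients)) patients <- sort(unique(reads$patient))
  ids <- sprintf("%s:%d-%d", rois$chrom, rois$start, rois$end)
  m <- matrix(0L, nrow = nrow(rois), ncol = length(patients),
              dimnames = list(ids, as.character(patients)))
  if (nrow(rois) == 0L || nrow(reads) == 0L) return(m)
  hits <- GenomicRanges::findOverlaps(as_granges(rois), as_granges(reads))
  if (length(hits)) {
    pat <- factor(reads$patient[S4Vectors::subjectHits(hits)],
                  levels = as.character(patients))
    tab <- table(factor(S4Vectors::queryHits(hits),
                        levels = seq_len(nrow(rois))), pat)
    m <- matrix(as.integer(tab), nrow = nrow(rois),
                dimnames = list(ids, as.character(patients)))
  }
  m
}

#' Merge significant regions into putative transcripts
#'
#' Regions that survive the survival screen are condensed by merging those
#' separated by less than `gap` bp (strict). When an expression matrix for
#' the regions is supplied, the within-merged-group and between-region
#' pairwise Pearson correlations are reported; strongly co-expressed
#' adjacent regions support treating a merged group as one transcript.
#'
#' @param rois Significant regions (chrom, start, end, count).
#' @param gap Merge distance in bp (default 1000; gaps of 999 merge, 1000
#'   does not).
#' @param expr Optional normalized expression matrix with rows named
#'   `chrom:start-end` matching the regions.
#' @return List with `merged` (condensed regions), `groups` (group index
#'   per input region), `median_r_within`, `median_r_between` (NA when
#'   undefined).
#' @export
post_fdr_merge <- function(rois, gap = 1000, expr = NULL) {
  if (inherits(expr, "ffpe_norm")) expr <- expr$values
  ord <- order(rois$chrom, rois$start, rois$end)
  x <- rois[ord, , drop = FALSE]
  grp <- integer(nrow(x))
  g <- 0L
  last_chrom <- ""
  run_end <- -Inf
  for (i in seq_len(nrow(x))) {
    if (x$chrom[i] != last_chrom || x$start[i] - run_end >= gap) {
      g <- g + 1L
      run_end <- x$end[i]
      last_chrom <- x$chrom[i]
    } else run_end <- max(run_end, x$end[i])
    grp[i] <- g
  }
  merged <- data.frame(
    chrom = x$chrom[!duplicated(grp)],
    start = as.integer(tapply(x$start, grp, min)),
    end = as.integer(tapply(x$end, grp, max)),
    count = as.integer(tapply(x$count, grp, sum)),
    n_members = as.integer(table(grp)),
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  med_within <- med_between <- NA_real_
  if (!is.null(expr)) {
    ids <- sprintf("%s:%d-%d", x$chrom, x$start, x$end)
    e <- expr[ids, , drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(e)))
    same <- outer(grp, grp, "==")
    ut <- upper.tri(cc)
    w <- cc[ut & same]
    b <- cc[ut & !same]
    if (length(w)) med_within <- stats::median(w, na.rm = TRUE)
    if (length(b)) med_between <- stats::median(b, na.rm = TRUE)
  }
  grp_out <- integer(nrow(rois))
  grp_out[ord] <- grp
  list(merged = merged, groups = grp_out,
       median_r_within = med_within, median_r_between = med_between)
}

#' Full intergenic transcript discovery pipeline
#'
#' Pooled reads -> islands -> cutoff estimation -> merged regions ->
#' retention filters -> intergenic classification. Returns every
#' intermediate so callers can report stage counts.
#'
#' @param reads Pooled reads with patient labels.
#' @param genes refFlat records.
#' @param n_patients Number of patients pooled.
#' @param candidates Candidate merge cutoffs (bp).
#' @param ... Passed to [filter_rois()].
#' @return List: islands, cutoff, scores, rois (merged + filtered),
#'   intergenic, counts (region x patient matrix).
#' @export
discover_intergenic <- function(reads, genes, n_patients,
                                candidates = c(0, 10, 20, 30, 50, 100),
                                ...) {
  islands <- build_islands(reads)
  est <- estimate_merge_cutoff(islands, genes, candidates)
  merged <- merge_islands(islands, est$cutoff, inclusive = TRUE)
  kept <- filter_rois(merged, n_patients, ...)
  inter <- classify_intergenic(kept, genes)
  counts <- roi_counts_per_patient(inter, reads)
  list(islands = islands, cutoff = est$cutoff, scores = est$scores,
       rois = kept, intergenic = inter, counts = counts)
}
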