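#' Build a small synthetic genome with genes and hidden intergenic loci
#'
#' Places non-overlapping multi-exon gene models and, in the remaining
#' intergenic space, hidden transcribed loci that an intergenic-discovery
#' run should recover. Hidden loci are kept well away from gene spans so
#' that, by construction, they pass the intergenic classification, and
#' their expression levels are set high enough to pass the retention
#' filters at the default sequencing depth.
#'
#' @param chrom_sizes Named integer vector of chromosome sizes
#'   (default chr1 = 200 kb, chr2 = 150 kb).
#' @param n_genes Number of gene models (default 12).
#' @param n_hidden Number of isolated hidden intergenic loci (default 6).
#' @param n_fragmented Number of fragmented locus pairs (default 2): two
#'   co-expressed intervals of one underlying transcript separated by a
#'   200-700 bp gap, the situation the post-screen < 1000 bp condensation
#'   step exists to repair.
#' @param seed Integer seed.
#' @return List of class `synthetic_genome`: `chrom_sizes`, `genes`
#'   (refFlat-style data frame), `loci` (chrom, start, end,
#'   reads_per_bp: expected reads per patient per bp at depth 1;
#'   pair: 0 for isolated loci, a shared index for fragment pairs).
#' @export
synthetic_genome <- function(chrom_sizes = c(chr1 = 200000L,
                                             chr2 = 150000L),
                             n_genes = 12L, n_hidden = 6L,
                             n_fragmented = 2L, seed) {
  set.seed(seed)
  margin <- 2000L
  place <- function(n, len_range, occupied) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(out) < n && tries < 10000L) {
      tries <- tries + 1L
      chrom <- sample(names(chrom_sizes), 1L)
      len <- if (len_range[1L] == len_range[2L]) len_range[1L]
        else sample(len_range[1L]:len_range[2L], 1L)
      maxs <- chrom_sizes[[chrom]] - len
      if (maxs <= 0L) next
      s <- sample.int(maxs, 1L)
      cand <- data.frame(chrom = chrom, start = s, end = s + len,
                         stringsAsFactors = FALSE)
      occ <- rbind(occupied, out)
      clash <- any(occ$chrom == chrom &
                     occ$start - margin < cand$end &
                     cand$start < occ$end + margin)
      if (!clash) out <- rbind(out, cand)
    }
    if (nrow(out) < n)
      stop("could not place ", n, " intervals; genome too small")
    out
  }
  none <- data.frame(chrom = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  gene_iv <- place(n_genes, c(2000L, 8000L), none)
  ex_starts <- vector("list", n_genes)
  ex_ends <- vector("list", n_genes)
  strands <- character(n_genes)
  for (i in seq_len(n_genes)) {
    g <- gene_iv[i, ]
    n_ex <- sample(2:5, 1L)
    cuts <- sort(sample(seq(g$start + 100L, g$end - 100L, by = 50L),
                        2L * n_ex - 2L))
    bounds <- c(g$start, cuts, g$end)
    ex_starts[[i]] <- as.integer(bounds[seq(1L, length(bounds) - 1L,
                                            by = 2L)])
    ex_ends[[i]] <- as.integer(bounds[seq(2L, length(bounds), by = 2L)])
    strands[i] <- sample(c("+", "-"), 1L)
  }
  genes <- data.frame(
    gene_name = sprintf("GENE%02d", seq_len(n_genes)),
    name = sprintf("NM_%06d", seq_len(n_genes)),
    chrom = gene_iv$chrom, strand = strands,
    tx_start = gene_iv$start, tx_end = gene_iv$end,
    cds_start = vapply(ex_starts, `[`, 0L, 1L),
    cds_end = vapply(ex_ends, function(e) e[length(e)], 0L),
    exon_count = lengths(ex_starts),
    stringsAsFactors = FALSE
  )
  genes$exon_starts <- ex_starts
  genes$exon_ends <- ex_ends

  loci <- place(n_hidden, c(300L, 800L), gene_iv)
  loci$reads_per_bp <- stats::runif(n_hidden, 0.15, 0.4)
  loci$pair <- 0L
  if (n_fragmented > 0L) {
    occupied <- rbind(gene_iv, loci[1:3])
    for (i in seq_len(n_fragmented)) {
      len1 <- sample(300:600, 1L)
      len2 <- sample(300:600, 1L)
      gap <- sample(200:700, 1L)     # < 1000 so condensation rejoins them
      meta <- place(1L, rep(len1 + gap + len2, 2L), occupied)
      frag <- data.frame(chrom = meta$chrom,
                         start = c(meta$start, meta$start + len1 + gap),
                         end = c(meta$start + len1, meta$end),
                         reads_per_bp = stats::runif(1L, 0.15, 0.4),
                         pair = i, stringsAsFactors = FALSE)
      occupied <- rbind(occupied, meta)
      loci <- rbind(loci, frag)
    }
  }
  rownames(loci) <- NULL

  structure(list(chrom_sizes = chrom_sizes, genes = genes, loci = loci),
            class = "synthetic_genome")
}

#' Simulate pooled 50 bp reads over a synthetic genome
#'
#' Reads are drawn along expressed gene exons and hidden intergenic loci:
#' per patient, the number of reads per transcription unit is Poisson
#' around the unit's expression level scaled by `depth_scale` and a
#' per-patient lognormal depth factor; read start positions are uniform
#' within the unit and reads are clipped at chromosome ends.
#'
#' @param genome A [synthetic_genome()].
#' @param n_patients Number of patients pooled.
#' @param depth_scale Global depth multiplier (> 0; 0 gives no reads).
#' @param seed Integer seed.
#' @param read_length Read length in bp (default 50).
#' @return Data frame of pooled reads: chrom, start, end, patient.
#' @export
simulate_read_islands <- function(genome, n_patients, depth_scale = 1,
                                  seed, read_length = 50L) {
  if (!inherits(genome, "synthetic_genome")) stop("not a synthetic genome")
  if (nrow(genome$genes) == 0L && nrow(genome$loci) == 0L)
    stop("empty genome: nothing to express")
  if (depth_scale < 0) stop("depth_scale must be >= 0")
  set.seed(seed)

  # expression units: every exon (at the gene's level) + hidden loci;
  # each unit carries a group label so fragments of one transcript (and
  # exons of one gene) share their per-patient expression variation
  loci <- genome$loci
  if (is.null(loci$pair)) loci$pair <- 0L
  loci$group <- ifelse(loci$pair > 0L, paste0("pair", loci$pair),
                       paste0("locus", seq_len(nrow(loci))))
  units <- do.call(rbind, c(
    lapply(seq_len(nrow(genome$genes)), function(i) {
      g <- genome$genes[i, ]
      lvl <- stats::runif(1L, 0.05, 0.2)   # reads per bp per patient
      data.frame(chrom = g$chrom, start = unlist(g$exon_starts),
                 end = unlist(g$exon_ends), reads_per_bp = lvl,
                 group = paste0("gene", i), stringsAsFactors = FALSE)
    }),
    list(loci[c("chrom", "start", "end", "reads_per_bp", "group")])
  ))
  if (depth_scale == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), patient = character(),
                      stringsAsFactors = FALSE))
  pat_depth <- stats::rlnorm(n_patients, -0.045, 0.3)
  # per-(transcription unit group, patient) biological expression factors
  groups <- unique(units$group)
  gfac <- matrix(stats::rlnorm(length(groups) * n_patients, -0.18, 0.6),
                 length(groups), n_patients,
                 dimnames = list(groups, NULL))
  out <- vector("list", nrow(units) * n_patients)
  k <- 0L
  for (u in seq_len(nrow(units))) {
    len <- units$end[u] - units$start[u]
    lam <- depth_scale * units$reads_per_bp[u] * len
    for (p in seq_len(n_patients)) {
      nr <- stats::rpois(1L, lam * pat_depth[p] * gfac[units$group[u], p])
      if (nr == 0L) next
      k <- k + 1L
      s <- units$start[u] + sample.int(len, nr, replace = TRUE) - 1L
      e <- pmin(s + read_length, genome$chrom_sizes[[units$chrom[u]]])
      out[[k]] <- data.frame(chrom = units$chrom[u], start = s, end = e,
                             patient = sprintf("P%03d", p),
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), patient = character(),
                      stringsAsFactors = FALSE))
  reads <- do.call(rbind, out[seq_len(k)])
  reads[order(reads$chrom, reads$start, reads$end), , drop = FALSE]
}
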