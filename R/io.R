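#' Read a UCSC refFlat gene annotation file
#'
#' Parses the 11-column tab-separated refFlat format (geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds).
#' Coordinates are 0-based half-open throughout the package, which is the
#' native refFlat convention. Exon coordinate lists may carry the UCSC
#' trailing comma.
#'
#' @param path Path to a refFlat.txt file (uncompressed, no header).
#' @return A data frame with one row per transcript record; `exon_starts` and
#'   `exon_ends` are list-columns of integer vectors of length `exon_count`.
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) stop("refFlat file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("refFlat file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 11L)
  if (length(bad)) {
    stop("refFlat parse error: expected 11 tab-separated columns at line",
         if (length(bad) > 1L) "s " else " ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  parse_list <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
  rec <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    tx_start <- as.integer(f[5L]); tx_end <- as.integer(f[6L])
    n_exon <- as.integer(f[9L])
    starts <- parse_list(f[10L]); ends <- parse_list(f[11L])
    if (is.na(tx_start) || is.na(tx_end) || tx_start >= tx_end)
      stop("refFlat record at line ", i, ": txStart must be < txEnd")
    if (length(starts) != n_exon || length(ends) != n_exon)
      stop("refFlat record at line ", i,
           ": exon list lengths do not match exonCount")
    if (any(starts >= ends))
      stop("refFlat record at line ", i, ": exon start >= end")
    if (is.unsorted(starts, strictly = TRUE) ||
        any(starts[-1L] < ends[-n_exon][seq_len(max(0L, n_exon - 1L))]))
      stop("refFlat record at line ", i,
           ": exons must be sorted and non-overlapping")
    if (starts[1L] < tx_start || ends[n_exon] > tx_end)
      stop("refFlat record at line ", i, ": exons outside [txStart, txEnd)")
    list(gene_name = f[1L], name = f[2L], chrom = f[3L], strand = f[4L],
         tx_start = tx_start, tx_end = tx_end,
         cds_start = as.integer(f[7L]), cds_end = as.integer(f[8L]),
         exon_count = n_exon, exon_starts = starts, exon_ends = ends)
  })
  out <- data.frame(
    gene_name = vapply(rec, `[[`, "", "gene_name"),
    name = vapply(rec, `[[`, "", "name"),
    chrom = vapply(rec, `[[`, "", "chrom"),
    strand = vapply(rec, `[[`, "", "strand"),
    tx_start = vapply(rec, `[[`, 0L, "tx_start"),
    tx_end = vapply(rec, `[[`, 0L, "tx_end"),
    cds_start = vapply(rec, `[[`, 0L, "cds_start"),
    cds_end = vapply(rec, `[[`, 0L, "cds_end"),
    exon_count = vapply(rec, `[[`, 0L, "exon_count"),
    stringsAsFactors = FALSE
  )
  out$exon_starts <- lapply(rec, `[[`, "exon_starts")
  out$exon_ends <- lapply(rec, `[[`, "exon_ends")
  out
}

#' Write refFlat records
#'
#' Inverse of [read_refflat()]; writes 11 tab-separated columns with the UCSC
#' trailing comma on exon lists.
#'
#' @param genes Data frame as returned by [read_refflat()].
#' @param path Output path.
#' @export
write_refflat <- function(genes, path) {
  fmt_list <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_name[i], genes$name[i], genes$chrom[i], genes$strand[i],
          genes$tx_start[i], genes$tx_end[i], genes$cds_start[i],
          genes$cds_end[i], genes$exon_count[i],
          fmt_list(genes$exon_starts[[i]]), fmt_list(genes$exon_ends[[i]]),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-by-sample count matrix
#'
#' Tab-separated, features in rows, first column the feature identifier,
#' remaining columns one per sample. Duplicate feature identifiers, negative
#' values and non-numeric cells are rejected.
#'
#' @param path Path to a TSV file.
#' @param nonnegative Reject negative values (TRUE for raw counts; use
#'   [read_expression_matrix()] for log-scale matrices).
#' @return Numeric matrix with feature row names and sample column names.
#' @export
read_count_matrix <- function(path, nonnegative = TRUE) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  if (file.size(path) == 0L) stop("count matrix file is empty: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("count matrix must have a feature-id column plus >=1 sample column")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature IDs in count matrix: ",
         paste(unique(utils::head(dup, 5L)), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in count matrix at row '",
             ids[bad[1L]], "', column '", names(vals)[j], "'")
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (nonnegative && any(m < 0, na.rm = TRUE)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at row '", rownames(m)[idx[1L]], "', column '",
         colnames(m)[idx[2L]], "'")
  }
  m
}

#' @rdname read_count_matrix
#' @export
read_expression_matrix <- function(path) {
  read_count_matrix(path, nonnegative = FALSE)
}

#' @rdname read_count_matrix
#' @param m Numeric matrix, features in rows.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample survival records
#'
#' CSV with columns `sample_id`, `time` (months to first recurrence, breast
#' cancer death, or censoring) and `event` (1 = recurrence/death, 0 =
#' censored). When `counts` is supplied the sample set must match the count
#' matrix columns exactly.
#'
#' @param path CSV path.
#' @param counts Optional count matrix whose column names must match.
#' @return Data frame with columns sample_id, time, event.
#' @export
read_survival <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival file must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    stop("survival times must be finite and > 0")
  if (!all(df$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1; offending values: ",
         paste(unique(df$event[!df$event %in% c(0, 1)]), collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in survival file")
  if (!is.null(counts)) {
    missing_surv <- setdiff(colnames(counts), df$sample_id)
    missing_cnt <- setdiff(df$sample_id, colnames(counts))
    if (length(missing_surv) || length(missing_cnt))
      stop("sample mismatch between survival records and count matrix; ",
           "missing from survival: ",
           paste(utils::head(missing_surv, 5L), collapse = ", "),
           "; missing from counts: ",
           paste(utils::head(missing_cnt, 5L), collapse = ", "))
    df <- df[match(colnames(counts), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' @rdname read_survival
#' @param surv Data frame with sample_id, time, event.
#' @export
write_survival <- function(surv, path) {
  utils::write.csv(surv[c("sample_id", "time", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates are written unchanged. Optional `name` and `score`/`count`
#' columns become BED columns 4 and 5.
#'
#' @param intervals Data frame with chrom, start, end and optionally
#'   name and score (or count, used as score).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    score <- if (!is.null(intervals$score)) intervals$score else intervals$count
    if (!is.null(score)) cols <- c(cols, list(score))
  }
  df <- do.call(data.frame, c(cols, list(stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' @param path BED path; columns beyond chrom/start/end are kept as
#'   name/score when present.
#' @return Data frame with chrom, start, end (0-based half-open) and any
#'   extra columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  if (any(df$start >= df$end)) stop("BED interval with start >= end")
  df
}

#' Write a co-expression graph to SIF or GraphML
#'
#' SIF lines are `A coexp B`, one per undirected edge, suitable for network
#' viewers. GraphML is written through igraph and round-trips edge weights.
#'
#' @param g A `coexp_graph` as returned by [correlation_graph()].
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
write_network <- function(g, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  ig <- as_igraph(g)
  if (format == "sif") {
    e <- g$edges
    lines <- if (nrow(e)) paste(e$from, "coexp", e$to) else character()
    writeLines(lines, path)
  } else {
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Read a SIF co-expression graph back as an edge list
#'
#' @param path SIF path with `A coexp B` lines.
#' @return Data frame with columns from, to.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) != 3L)) stop("malformed SIF line")
  data.frame(from = vapply(parts, `[`, "", 1L),
             to = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
}
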