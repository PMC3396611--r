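#' Log2-transform raw counts with the zero-count convention
#'
#' Counts of 0 are assigned a log2 value of 0 (the same value as a count of
#' 1). This deliberate collision is part of the transform's definition and is
#' kept rather than patched with pseudocounts; downstream statistics operate
#' on the values as defined.
#'
#' @param raw Non-negative count matrix, features in rows.
#' @return Numeric matrix of log2 values, same dimnames.
#' @export
log2_transform <- function(raw) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  if (any(raw < 0, na.rm = TRUE)) stop("counts must be non-negative")
  out <- raw
  pos <- raw >= 1
  out[pos] <- log2(raw[pos])
  out[!pos] <- 0
  out
}

#' Exclude features never reaching a minimum count
#'
#' A feature is retained iff its maximum count over all samples is at least
#' `threshold`. Applied to the full cohort this is the screen's only
#' feature-level exclusion before normalization.
#'
#' @param raw Count matrix, features in rows.
#' @param threshold Minimum maximum count (default 5).
#' @return List with `retained` (feature IDs kept), `n_removed`, and `keep`
#'   (logical vector aligned to rows).
#' @export
max_count_filter <- function(raw, threshold = 5) {
  stopifnot(threshold >= 1)
  mx <- apply(raw, 1L, max)
  keep <- mx >= threshold
  list(retained = rownames(raw)[keep],
       n_removed = sum(!keep),
       keep = keep)
}

#' Third-quartile normalization of log2 counts
#'
#' Each sample's log2 values are shifted by (cohort mean Q3 - sample Q3),
#' where Q3 is the per-sample third quartile of the log2 counts of a
#' reference feature class. RefSeq features serve as the reference for
#' RefSeq and intergenic matrices; intronic features for intronic matrices.
#' After normalization every sample's Q3 over the reference features equals
#' the cohort mean Q3 exactly (when the matrix is its own reference).
#'
#' @param m Log2 matrix to normalize (features in rows).
#' @param reference Log2 matrix of the reference feature class with the same
#'   samples; defaults to `m` itself.
#' @param reference_class Label recorded with the result
#'   ("refseq", "intron", or "intergenic").
#' @param type Quantile type passed to [stats::quantile()]; default 7
#'   (linear interpolation between order statistics).
#' @return An object of class `ffpe_norm`: list with `values` (normalized
#'   matrix), `reference_class`, `q3_per_sample` (post-normalization),
#'   `cohort_mean_q3`, and `shift` (per-sample additive shift applied).
#' @export
third_quartile_normalize <- function(m, reference = m,
                                     reference_class = "refseq",
                                     type = 7) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!is.matrix(reference)) reference <- as.matrix(reference)
  if (ncol(reference) != ncol(m))
    stop("reference matrix must have the same samples as m")
  if (nrow(reference) == 0L) stop("reference feature set is empty")
  if (nrow(reference) == 1L)
    warning("single-feature reference set: quartile is degenerate")
  q3 <- apply(reference, 2L, stats::quantile, probs = 0.75,
              names = FALSE, type = type)
  mean_q3 <- mean(q3)
  shift <- mean_q3 - q3
  out <- sweep(m, 2L, shift, "+")
  structure(list(values = out,
                 reference_class = reference_class,
                 q3_per_sample = q3 + shift,
                 cohort_mean_q3 = mean_q3,
                 shift = shift),
            class = "ffpe_norm")
}

#' @export
print.ffpe_norm <- function(x, ...) {
  cat("Third-quartile normalized matrix:", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  cat("  reference class:", x$reference_class,
      " cohort mean Q3:", format(x$cohort_mean_q3, digits = 4), "\n")
  cat("  per-sample shift range: [",
      format(min(x$shift), digits = 3), ", ",
      format(max(x$shift), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Relative log expression (RLE) diagnostic
#'
#' RLE of feature f in sample s is the log2 value minus the within-sample
#' median over features. For an effectively normalized cohort the per-sample
#' RLE distributions are centered on zero and tight.
#'
#' @param values Log2 (usually normalized) matrix, >= 2 features.
#' @return List with `rle` (matrix of RLE values) and `summary` (data frame
#'   of per-sample median and IQR).
#' @export
rle_diagnostic <- function(values) {
  if (inherits(values, "ffpe_norm")) values <- values$values
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) < 2L) stop("RLE needs at least 2 features")
  med <- apply(values, 2L, stats::median)
  rle <- sweep(values, 2L, med, "-")
  summ <- data.frame(
    sample_id = colnames(values) %||% as.character(seq_len(ncol(values))),
    median = apply(rle, 2L, stats::median),
    iqr = apply(rle, 2L, stats::IQR),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(rle = rle, summary = summ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
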