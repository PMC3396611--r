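#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments, Lin's original definition. Measures
#' agreement with the identity line, penalizing location and scale shifts
#' as well as scatter, so |rho_c| <= |Pearson r| always.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return The concordance correlation coefficient.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0)
    stop("both vectors are constant: CCC undefined")
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Normalize RT-PCR crossing-threshold values
#'
#' Reference-normalized expression on the C_T scale: each measurement is
#' subtracted from the gene's cohort median C_T, so 0 is the cohort median
#' and +1 means one PCR cycle more expression (C_T counts down as
#' expression goes up).
#'
#' @param ct Numeric vector of C_T values for one gene across the cohort,
#'   or a gene x sample matrix (normalized per gene/row).
#' @return Normalized expression, same shape as input.
#' @export
ct_normalize <- function(ct) {
  if (is.matrix(ct)) {
    if (any(!is.finite(ct))) stop("C_T values must be finite")
    med <- apply(ct, 1L, stats::median)
    return(sweep(-ct, 1L, med, "+"))
  }
  if (any(!is.finite(ct))) stop("C_T values must be finite")
  stats::median(ct) - ct
}

#' Cross-platform agreement in prognostic classification
#'
#' Classifies every feature as prognostic (p < alpha) on each of two
#' platforms, tabulates the 2x2 agreement, and tests it with Fisher's
#' exact test. An optional stratification (e.g. abundance bins) produces
#' per-stratum tables, since agreement typically decays with decreasing
#' transcript abundance.
#'
#' @param p_a,p_b P-value vectors over the same feature universe.
#' @param alpha Significance threshold defining "prognostic" (default 0.05).
#' @param strata Optional factor splitting features into strata.
#' @return List of class `agreement_table`: `table` (2x2), `odds_ratio`
#'   (Inf flagged via `or_unbounded`), `p` (Fisher exact), and `strata`
#'   (named list of per-stratum results) when stratified.
#' @export
prognostic_agreement <- function(p_a, p_b, alpha = 0.05, strata = NULL) {
  stopifnot(length(p_a) == length(p_b))
  if (length(p_a) == 0L) stop("empty feature universe")
  sig_a <- factor(p_a < alpha, levels = c(TRUE, FALSE))
  sig_b <- factor(p_b < alpha, levels = c(TRUE, FALSE))
  tab <- table(platform_a = sig_a, platform_b = sig_b)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ft <- stats::fisher.test(tab)
  out <- list(table = tab,
              odds_ratio = or,
              or_unbounded = !is.finite(or),
              p = ft$p.value)
  if (!is.null(strata)) {
    out$strata <- lapply(split(seq_along(p_a), strata), function(idx)
      prognostic_agreement(p_a[idx], p_b[idx], alpha = alpha))
  }
  class(out) <- "agreement_table"
  out
}

#' @export
print.agreement_table <- function(x, ...) {
  print(x$table)
  cat("odds ratio:", if (x$or_unbounded) "unbounded (empty off-diagonal)"
      else format(x$odds_ratio, digits = 4),
      "  Fisher exact p:", format.pval(x$p, digits = 3), "\n")
  invisible(x)
}

#' Concordance statistics for hazard-ratio scatter comparisons
#'
#' Lin CCC and Pearson r of two sets of hazard ratios on the log2 scale,
#' the scale on which cross-platform hazard-ratio scatter plots are drawn.
#'
#' @param hr_a,hr_b Paired hazard ratios (> 0) from two platforms.
#' @return List with `lin_ccc` and `pearson_r`.
#' @export
hazard_ratio_scatter_stats <- function(hr_a, hr_b) {
  stopifnot(length(hr_a) == length(hr_b), all(hr_a > 0), all(hr_b > 0))
  x <- log2(hr_a); y <- log2(hr_b)
  list(lin_ccc = lin_ccc(x, y),
       pearson_r = stats::cor(x, y))
}
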