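#' Storey q-values
#'
#' Estimates the proportion of true nulls as
#' `pi0 = #\{p > lambda\} / ((1 - lambda) m)`, clipped to (0, 1], and converts
#' p-values to q-values with the usual step-up monotone enforcement
#' `q_(i) = min_(j >= i) pi0 m p_(j) / j`, capped at 1.
#'
#' @param p P-values in \[0, 1\].
#' @param lambda Tuning parameter in (0, 1); default 0.5.
#' @return List with `q` (q-values, same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  m <- length(p)
  pi0 <- sum(p > lambda) / ((1 - lambda) * m)
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) pi0 <- 1 / m   # keep in (0, 1]; all p below lambda
  ord <- order(p)
  q_ord <- pi0 * m * p[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q_ord <- pmin(q_ord, 1)
  q <- numeric(m)
  q[ord] <- q_ord
  list(q = q, pi0 = pi0)
}

#' TDRDA maximum lower bounds on the standardized hazard ratio
#'
#' For each candidate lower bound B >= 1, tests H0: |beta| <= log B with a
#' shifted Wald test and computes Storey q-values per bound; a feature
#' belongs to the B-set when its q-value is below `fdr`. The reported value
#' is the largest bound for which the feature is a member (with nestedness
#' enforced along the grid, so B-set membership implies membership at every
#' smaller bound), or NA when the feature is not even in the B = 1 set.
#'
#' The default (non-directional) p-value is
#' `min(1, 2 (1 - Phi((|beta| - log B) / se)))`; the factor 2 accounts for
#' the two screening directions so that at B = 1 membership coincides
#' exactly with the ordinary two-sided screen at the same FDR. Setting
#' `directional = TRUE` instead runs the two one-sided screens separately
#' (each at `fdr`) and takes a feature's bound from its own direction.
#'
#' @param beta Per-SD log hazard estimates.
#' @param se Robust standard errors.
#' @param fdr FDR level (default 0.10).
#' @param grid Ascending candidate bounds starting at 1.
#' @param lambda Storey tuning parameter, applied per bound.
#' @param directional Use per-direction one-sided screens instead of the
#'   two-direction combined test.
#' @return Numeric vector of maximum qualifying bounds (NA when none).
#' @export
tdrda_lower_bounds <- function(beta, se, fdr = 0.10,
                               grid = seq(1, 2, by = 0.05),
                               lambda = 0.5, directional = FALSE) {
  if (is.unsorted(grid) || grid[1L] < 1)
    stop("grid must be ascending and start at a bound >= 1")
  m <- length(beta)
  member <- rep(TRUE, m)
  best <- rep(NA_real_, m)
  for (B in grid) {
    shift <- log(B)
    if (directional) {
      p_up <- stats::pnorm((beta - shift) / se, lower.tail = FALSE)
      p_dn <- stats::pnorm((-beta - shift) / se, lower.tail = FALSE)
      in_up <- storey_qvalues(p_up, lambda)$q < fdr
      in_dn <- storey_qvalues(p_dn, lambda)$q < fdr
      in_B <- in_up | in_dn
    } else {
      pB <- pmin(1, 2 * stats::pnorm((abs(beta) - shift) / se,
                                     lower.tail = FALSE))
      in_B <- storey_qvalues(pB, lambda)$q < fdr
    }
    member <- member & in_B            # enforce nested sets along the grid
    best[member] <- B
    if (!any(member)) break
  }
  best
}

#' Regression-to-the-mean correction of screened effect estimates
#'
#' Empirical-Bayes normal-normal shrinkage: the between-feature effect
#' variance is estimated as `tau2 = max(0, Var(beta) - mean(se^2))` and each
#' estimate is pulled toward the cross-feature mean with weight
#' `tau2 / (tau2 + se_i^2)`. Selection of extreme estimates in a
#' genome-wide screen inflates their apparent effect sizes; the shrunken
#' values are the corrected standardized log hazards.
#'
#' @param beta Per-SD log hazard estimates (>= 10 features).
#' @param se Robust standard errors.
#' @return Vector of corrected log hazards (exponentiate for corrected
#'   standardized hazard ratios).
#' @export
rtm_correct <- function(beta, se) {
  if (length(beta) < 10L)
    stop("regression-to-the-mean correction needs >= 10 features")
  mu <- mean(beta)
  tau2 <- max(0, stats::var(beta) - mean(se^2))
  mu + (beta - mu) * tau2 / (tau2 + se^2)
}
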