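#' Call estrogen-receptor status from ESR1 and PGR expression
#'
#' ER status is positive iff normalized ESR1 expression is at or above the
#' ESR1 cutoff. When a cutoff is not supplied it is set automatically at
#' the midpoint between the two component means of a two-component Gaussian
#' mixture fitted to the marker (EM with deterministic initialization at
#' the 25th/75th percentiles), an algorithmic stand-in for drawing the line
#' by eye on the ESR1/PGR scatter. PGR is used the same way to flag
#' biologically unusual PGR+/ER- and PGR-/ER+ discordant samples.
#'
#' @param esr1,pgr Normalized expression vectors, aligned by sample.
#' @param sample_id Optional sample identifiers.
#' @param esr1_cutoff,pgr_cutoff Explicit cutoffs; NULL (default) fits the
#'   mixture.
#' @return Data frame of class `er_calls`: sample_id, esr1, pgr, status
#'   ("positive"/"negative"), pgr_positive, discordant; attributes
#'   `esr1_cutoff`, `pgr_cutoff`.
#' @export
call_er_status <- function(esr1, pgr, sample_id = NULL,
                           esr1_cutoff = NULL, pgr_cutoff = NULL) {
  stopifnot(length(esr1) == length(pgr))
  if (is.null(sample_id)) sample_id <- names(esr1) %||%
      paste0("S", seq_along(esr1))
  if (is.null(esr1_cutoff)) esr1_cutoff <- mixture_midpoint(esr1, "ESR1")
  if (is.null(pgr_cutoff)) pgr_cutoff <- mixture_midpoint(pgr, "PGR")
  er_pos <- esr1 >= esr1_cutoff
  pgr_pos <- pgr >= pgr_cutoff
  out <- data.frame(
    sample_id = sample_id,
    esr1 = esr1,
    pgr = pgr,
    status = ifelse(er_pos, "positive", "negative"),
    pgr_positive = pgr_pos,
    discordant = er_pos != pgr_pos,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "esr1_cutoff") <- esr1_cutoff
  attr(out, "pgr_cutoff") <- pgr_cutoff
  class(out) <- c("er_calls", "data.frame")
  out
}

# Two-component univariate Gaussian mixture by EM; returns the midpoint
# between the component means. Deterministic: means initialized at the
# 25th/75th percentiles, equal variances and weights.
mixture_midpoint <- function(x, marker = "marker", max_iter = 500L,
                             tol = 1e-8) {
  if (length(x) < 10L)
    stop("too few samples to fit a mixture for ", marker,
         "; supply an explicit cutoff")
  mu <- as.numeric(stats::quantile(x, c(0.25, 0.75), type = 7))
  sg <- rep(stats::sd(x), 2L)
  pi1 <- 0.5
  loglik_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1L], sg[1L])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2L], sg[2L])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot)))
      stop("mixture fit degenerate for ", marker,
           "; supply an explicit cutoff")
    g <- d1 / tot
    pi1 <- mean(g)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sg <- sqrt(c(sum(g * (x - mu[1L])^2) / sum(g),
                 sum((1 - g) * (x - mu[2L])^2) / sum(1 - g)))
    sg <- pmax(sg, 1e-6 * stats::sd(x))
    loglik <- sum(log(tot))
    if (is.finite(loglik_old) && abs(loglik - loglik_old) <
        tol * (abs(loglik_old) + tol)) break
    loglik_old <- loglik
  }
  sep <- abs(diff(mu)) / sqrt(mean(sg^2))
  if (min(pi1, 1 - pi1) < 0.02 || sep < 0.5)
    stop("distribution of ", marker, " is not clearly bimodal ",
         "(mixture collapse); supply an explicit cutoff")
  mean(mu)
}

#' @export
print.er_calls <- function(x, ...) {
  cat("ER status calls: ", sum(x$status == "positive"), " positive / ",
      sum(x$status == "negative"), " negative (ESR1 cutoff ",
      format(attr(x, "esr1_cutoff"), digits = 4), ")\n", sep = "")
  if (any(x$discordant))
    cat("  ", sum(x$discordant), " sample(s) ESR1/PGR discordant\n")
  invisible(x)
}
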