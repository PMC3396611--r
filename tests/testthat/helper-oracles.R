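# Independent brute-force oracles used to validate the fast implementations.

# islands as connected components of the strict-overlap graph, found by
# breadth-first search on an explicit adjacency matrix (reads overlap iff
# start_i < end_j and start_j < end_i; abutting reads are not adjacent)
coverage_islands_oracle <- function(reads) {
  out <- lapply(split(reads, reads$chrom), function(r) {
    n <- nrow(r)
    adj <- outer(r$start, r$end, "<") & t(outer(r$start, r$end, "<"))
    comp <- integer(n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (comp[i] > 0L) next
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        if (comp[v] > 0L) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
    data.frame(chrom = r$chrom[1L],
               start = as.integer(tapply(r$start, comp, min)),
               end = as.integer(tapply(r$end, comp, max)),
               count = as.integer(table(comp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(n^2) transitive-closure merge: repeatedly merge any mergeable pair
transitive_merge_oracle <- function(islands, cutoff, inclusive = FALSE) {
  x <- islands
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(x)) {
      j <- i + 1L
      while (j <= nrow(x)) {
        if (x$chrom[i] == x$chrom[j]) {
          gap <- max(x$start[i], x$start[j]) - min(x$end[i], x$end[j])
          hit <- if (inclusive) gap <= cutoff else gap < cutoff
          if (hit) {
            x$start[i] <- min(x$start[i], x$start[j])
            x$end[i] <- max(x$end[i], x$end[j])
            x$count[i] <- x$count[i] + x$count[j]
            x <- x[-j, , drop = FALSE]
            merged_any <- TRUE
            next
          }
        }
        j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# explicit Efron partial log-likelihood for one covariate
efron_loglik <- function(beta, z, time, event) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    wD <- exp(beta * z[D])
    wR <- exp(beta * z[R])
    ll <- ll + beta * sum(z[D])
    for (l in 0:(d - 1L))
      ll <- ll - log(sum(wR) - (l / d) * sum(wD))
  }
  ll
}

grid_cox_oracle <- function(z, time, event) {
  stats::optimize(function(b) efron_loglik(b, z, time, event),
                  interval = c(-5, 5), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1L, ]); n2 <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  support <- max(0L, k - n2):min(m, k)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_reads <- function(n, chrom_len = 10000L, chroms = "chr1",
                         read_len = 50L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - read_len, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = start, end = start + read_len,
             patient = sample(sprintf("P%02d", 1:4), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_islands <- function(n, chrom_len = 50000L, chroms = c("chr1", "chr2")) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len, n, replace = TRUE) - 1L
  len <- sample(20:400, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             count = sample(1:50, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# shared small cohort so expensive simulation happens once per run
toy_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(
        n_patients = 60L, n_features = 400L, n_events_target = 20L,
        block_sizes = c(10L, 5L), block_rho = 0.9, seed = 101L))
    cache
  }
})
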