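#' Abundance-bin identification report
#'
#' Bins features by their median raw count across patients (<10, 10-99,
#' 100-999, >=1000) and reports, per bin, how many features the screen
#' identified at the FDR threshold, with percentages rounded to one
#' decimal, plus a totals row.
#'
#' @param raw Raw count matrix (features x samples).
#' @param q Named (or screen-ordered) q-value vector; `screen` may be
#'   passed instead.
#' @param screen Optional `screen_result` data frame (used for q-values,
#'   matched by feature_id).
#' @param fdr FDR threshold (default 0.10).
#' @return Data frame: bin, n, n_identified, pct_identified; last row is
#'   the total.
#' @export
abundance_bin_report <- function(raw, q = NULL, screen = NULL, fdr = 0.10) {
  if (is.null(q)) {
    if (is.null(screen)) stop("supply q-values or a screen result")
    q <- stats::setNames(screen$q, screen$feature_id)[rownames(raw)]
  } else if (!is.null(names(q))) {
    q <- q[rownames(raw)]
  }
  if (length(q) != nrow(raw))
    stop("q-values do not align with the count matrix rows")
  med <- apply(raw, 1L, stats::median)
  bin <- cut(med, breaks = c(-Inf, 10, 100, 1000, Inf), right = FALSE,
             labels = c("<10", "10-99", "100-999", ">=1000"))
  ident <- !is.na(q) & q < fdr
  n <- as.integer(table(bin))
  n_id <- as.integer(tapply(ident, bin, sum, default = 0L))
  out <- data.frame(
    bin = c(levels(bin), "Total"),
    n = c(n, sum(n)),
    n_identified = c(n_id, sum(n_id)),
    stringsAsFactors = FALSE
  )
  out$pct_identified <- round(100 * out$n_identified / pmax(out$n, 1L), 1)
  out$pct_identified[out$n == 0L] <- NA_real_
  out
}

#' Run the full screening pipeline on a synthetic or supplied cohort
#'
#' Orchestrates cohort synthesis (or loading), third-quartile
#' normalization, the genome-wide Cox screen, intergenic discovery on a
#' synthetic genome, the co-expression network of identified features, and
#' a JSON run summary. Stages can be toggled off; one seed governs all
#' stochastic stages.
#'
#' @param config Named list (or YAML path) with elements: `seed`;
#'   optional `cohort` (arguments for [cohort_config()]); `fdr`, `lambda`,
#'   `r_threshold`; `stages` (logical toggles: discover, network);
#'   `out_dir`.
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("pipeline config requires a seed")
  fdr <- config$fdr %||% 0.10
  lambda <- config$lambda %||% 0.5
  r_thr <- config$r_threshold %||% 0.6
  stages <- config$stages %||% list()
  do_discover <- stages$discover %||% TRUE
  do_network <- stages$network %||% TRUE
  out_dir <- config$out_dir %||% tempfile("ffpescreen_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_file, append = TRUE, sep = "")
    message(line)
  }
  summary <- list(seed = config$seed)

  logmsg("stage synth: generating cohort")
  cohort_args <- config$cohort %||% list()
  cohort_args$seed <- config$seed
  cohort <- simulate_cohort(do.call(cohort_config, cohort_args))
  write_cohort(cohort, file.path(out_dir, "cohort"))
  summary$n_patients <- ncol(cohort$counts)
  summary$n_features_raw <- nrow(cohort$counts)
  summary$n_events <- sum(cohort$survival$event)

  logmsg("stage normalize: max-count filter + third-quartile normalization")
  filt <- max_count_filter(cohort$counts, threshold = 5)
  counts <- cohort$counts[filt$keep, , drop = FALSE]
  summary$n_features_retained <- nrow(counts)
  norm <- third_quartile_normalize(log2_transform(counts))
  rle <- rle_diagnostic(norm)
  summary$rle_median_range <- range(rle$summary$median)
  write_count_matrix(round(norm$values, 4), file.path(out_dir, "norm.tsv"))

  logmsg("stage screen: univariate Cox screen over ",
         nrow(counts), " features")
  scr <- survival_screen(norm, cohort$survival, fdr = fdr, lambda = lambda)
  utils::write.table(scr, file.path(out_dir, "screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary$pi0 <- attr(scr, "pi0")
  summary$n_identified <- sum(scr$q < fdr)
  bin_tab <- abundance_bin_report(counts, screen = scr, fdr = fdr)
  utils::write.table(bin_tab, file.path(out_dir, "abundance_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$abundance_bins <- bin_tab

  if (do_discover) {
    logmsg("stage discover: intergenic transcript discovery")
    genome <- synthetic_genome(seed = config$seed + 1L)
    reads <- simulate_read_islands(genome, n_patients = 8L,
                                   depth_scale = 1, seed = config$seed + 2L)
    disc <- discover_intergenic(reads, genome$genes, n_patients = 8L)
    write_bed(transform(disc$intergenic,
                        name = sprintf("ROI%03d",
                                       seq_len(nrow(disc$intergenic)))),
              file.path(out_dir, "intergenic.bed"))
    summary$n_islands <- nrow(disc$islands)
    summary$merge_cutoff <- disc$cutoff
    summary$n_rois <- nrow(disc$rois)
    summary$n_intergenic <- nrow(disc$intergenic)
  }

  if (do_network) {
    logmsg("stage network: co-expression graph of identified features")
    hits <- scr$feature_id[scr$q < fdr]
    if (length(hits) >= 2L) {
      g <- correlation_graph(norm, features = hits, threshold = r_thr)
      write_network(g, file.path(out_dir, "network.sif"), format = "sif")
      comp <- graph_components(g)
      summary$network_nodes <- length(g$nodes)
      summary$network_edges <- nrow(g$edges)
      summary$component_sizes <- utils::head(comp$sizes, 10L)
    } else {
      summary$network_nodes <- 0L
      summary$network_edges <- 0L
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("pipeline complete; outputs in ", out_dir)
  invisible(summary)
}
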