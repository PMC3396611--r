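#' Thresholded co-expression graph
#'
#' Computes all pairwise Pearson correlations of the selected features on
#' normalized log2 expression and keeps an undirected edge wherever
#' R exceeds the threshold (strictly; positive correlations only by
#' default). Features that co-express with no other feature are dropped, so
#' every node has degree >= 1.
#'
#' @param values Normalized matrix (features x samples) or `ffpe_norm`.
#' @param features Feature IDs to consider; default all rows.
#' @param threshold Correlation threshold (default 0.6, edge iff R > 0.6).
#' @param use_abs Threshold |R| instead of R (captures strong negative
#'   co-expression too).
#' @return Object of class `coexp_graph`: list with `nodes`, `edges` (data
#'   frame from, to, weight), and `threshold`.
#' @export
correlation_graph <- function(values, features = NULL, threshold = 0.6,
                              use_abs = FALSE) {
  if (inherits(values, "ffpe_norm")) values <- values$values
  if (is.null(features)) features <- rownames(values)
  missing_feat <- setdiff(features, rownames(values))
  if (length(missing_feat))
    stop("features absent from expression matrix: ",
         paste(utils::head(missing_feat, 5L), collapse = ", "))
  if (ncol(values) < 3L) stop("need >= 3 samples for correlation")
  x <- values[features, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) excluded from the graph")
    x <- x[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(x))
  crit <- if (use_abs) abs(cc) else cc
  sel <- which(upper.tri(cc) & crit > threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(cc)[sel[, 1L]],
    to = rownames(cc)[sel[, 2L]],
    weight = cc[sel],
    stringsAsFactors = FALSE
  )
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "coexp_graph")
}

as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = if (length(g$nodes))
                                        g$nodes else NULL)
  ig
}

#' Connected components and node degrees of a co-expression graph
#'
#' @param g A `coexp_graph`.
#' @return List with `components` (data frame node, component), `sizes`
#'   (component sizes, largest first), and `degree` (named vector).
#' @export
graph_components <- function(g) {
  if (!length(g$nodes))
    return(list(components = data.frame(node = character(),
                                        component = integer()),
                sizes = integer(), degree = integer()))
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  deg <- igraph::degree(ig)
  list(
    components = data.frame(node = names(comp$membership),
                            component = as.integer(comp$membership),
                            stringsAsFactors = FALSE),
    sizes = sort(as.integer(comp$csize), decreasing = TRUE),
    degree = deg
  )
}

#' @export
print.coexp_graph <- function(x, ...) {
  cat("Co-expression graph: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (R > ", x$threshold, ")\n", sep = "")
  invisible(x)
}
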