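# ROI-level network extraction: Bonferroni-corrected correlation graph over
# ROI mean time series and seed-conditioned maximal-clique networks.

#' ROI correlation graph
#'
#' Pairwise Pearson correlation of the ROI mean time series, significance
#' assessed on the t-transformed correlation at level `alpha` with
#' Bonferroni correction over the `m (m - 1) / 2` tested pairs; significant
#' pairs become edges of an undirected graph.
#'
#' @param clusters an `"snc_clusters"` object with `roi_mean_series`, or an
#'   m x T matrix of ROI mean time series.
#' @param alpha significance level (default 0.05).
#' @return object of class `"roi_graph"`: list with `adjacency` (m x m 0/1,
#'   zero diagonal), `correlation`, `p_adj`, `alpha`, `n_tests`.
#' @export
roi_graph <- function(clusters, alpha = 0.05) {
  series <- if (inherits(clusters, "snc_clusters")) clusters$roi_mean_series
            else as.matrix(clusters)
  if (is.null(series)) stop("clusters carry no ROI mean series")
  m <- nrow(series)
  if (m < 2L) stop("need at least 2 ROIs")
  n_t <- ncol(series)
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0)) warning("constant ROI mean series excluded")
  cm <- matrix(NA_real_, m, m)
  live <- sds > 0
  if (sum(live) >= 2L)
    cm[live, live] <- stats::cor(t(series[live, , drop = FALSE]))
  n_tests <- m * (m - 1) / 2
  r <- pmin(pmax(cm, -1), 1)
  tt <- r * sqrt((n_t - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n_t - 2)
  p[abs(r) >= 1] <- 0
  p_adj <- pmin(p * n_tests, 1)
  adj <- (p_adj < alpha) * 1L
  adj[is.na(adj)] <- 0L
  diag(adj) <- 0L
  structure(list(adjacency = adj, correlation = cm, p_adj = p_adj,
                 alpha = alpha, n_tests = n_tests),
            class = "roi_graph")
}

#' @export
print.roi_graph <- function(x, ...) {
  cat(sprintf("roi_graph: %d ROIs, %d significant edges (Bonferroni alpha = %g)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$alpha))
  invisible(x)
}

#' Seed-conditioned maximal-clique network
#'
#' Enumerates the maximal cliques of the ROI graph that contain the seed ROI
#' and returns the largest one — the largest set of mutually significantly
#' connected ROIs including the seed, interpreted as the seed's connectivity
#' network. Ties between equal-size maximal cliques are broken by the
#' lexicographically smallest sorted id set, so the result is deterministic.
#'
#' @param graph a [roi_graph()] (or any list with an `adjacency` matrix).
#' @param seed_roi ROI index (1-based).
#' @return sorted integer vector of ROI ids; the seed itself if isolated.
#' @export
seed_network <- function(graph, seed_roi) {
  adj <- graph$adjacency
  m <- nrow(adj)
  seed_roi <- as.integer(seed_roi)
  if (seed_roi < 1L || seed_roi > m) stop("seed ROI not in graph")
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  cl <- igraph::max_cliques(g)
  cl <- Filter(function(v) seed_roi %in% as.integer(v), cl)
  if (length(cl) == 0L) return(seed_roi)
  sets <- lapply(cl, function(v) sort(as.integer(v)))
  sizes <- lengths(sets)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    keys <- vapply(sets[best],
                   function(s) paste(sprintf("%09d", s), collapse = ","),
                   character(1))
    best <- best[order(keys)[1]]
  }
  sets[[best]]
}

#' Write an ROI graph as GraphML and a TSV edge list
#'
#' @param graph a [roi_graph()].
#' @param prefix output path prefix (`<prefix>.graphml`,
#'   `<prefix>_edges.tsv`).
#' @return invisibly, the paths written.
#' @export
write_roi_graph <- function(graph, prefix) {
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency != 0,
                                           mode = "undirected")
  gp <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gp, format = "graphml")
  e <- which(upper.tri(graph$adjacency) & graph$adjacency != 0,
             arr.ind = TRUE)
  df <- data.frame(roi_i = e[, 1], roi_j = e[, 2],
                   r = graph$correlation[e], p_adjusted = graph$p_adj[e])
  tp <- paste0(prefix, "_edges.tsv")
  utils::write.table(df, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = gp, edges = tp))
}
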