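#' Weighted node metrics
#'
#' Node-level summaries of a weighted association network, all defined on a
#' symmetric non-negative weight matrix with zero diagonal.
#'
#' * `weighted_degree()` (strength): the sum of a node's edge weights — how
#'   gregarious the individual is overall.
#' * `eigenvector_centrality()`: leading eigenvector of the weight matrix,
#'   rescaled so the maximum entry is 1; high values mean strong connections
#'   to strongly connected others. On a disconnected network the centrality
#'   is computed on the largest connected component, with zeros elsewhere
#'   and a diagnostic warning.
#' * `weighted_betweenness()`: number of shortest paths through each node,
#'   with edge lengths `1/weight` so that strong associations make short
#'   paths; ties between equal-length paths are split fractionally, counts
#'   are over unordered pairs and unnormalised. Zero-weight edges are
#'   absent; disconnected pairs contribute nothing.
#'
#' @param weights Symmetric non-negative N x N matrix, zero diagonal.
#' @return A named numeric vector, one value per node.
#' @examples
#' net <- generate_true_network(10, seed = 1)
#' weighted_degree(net$weights)
#' @name node_metrics
NULL

check_weight_matrix <- function(weights) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    abort("`weights` must be a square matrix")
  if (any(weights < 0)) abort("`weights` must be non-negative")
  if (any(abs(weights - t(weights)) > 1e-12)) abort("`weights` must be symmetric")
  invisible(weights)
}

weight_graph <- function(weights) {
  igraph::graph_from_adjacency_matrix(weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' @rdname node_metrics
#' @export
weighted_degree <- function(weights) {
  check_weight_matrix(weights)
  d <- rowSums(weights)
  names(d) <- rownames(weights)
  d
}

#' @rdname node_metrics
#' @export
eigenvector_centrality <- function(weights) {
  check_weight_matrix(weights)
  if (all(weights == 0)) abort("eigenvector centrality undefined on an empty network")
  g <- weight_graph(weights)
  comp <- igraph::components(g)
  keep <- seq_len(nrow(weights))
  if (comp$no > 1L) {
    warn("network is disconnected; centrality computed on the largest component, zeros elsewhere")
    biggest <- which.max(comp$csize)
    keep <- which(comp$membership == biggest)
    g <- igraph::induced_subgraph(g, keep)
  }
  cen <- numeric(nrow(weights))
  cen[keep] <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  names(cen) <- rownames(weights)
  cen
}

#' @rdname node_metrics
#' @export
weighted_betweenness <- function(weights) {
  check_weight_matrix(weights)
  g <- weight_graph(weights)
  bw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                            directed = FALSE, normalized = FALSE)
  setNames(unname(bw), rownames(weights))
}

metric_fun <- function(metric) {
  switch(metric,
    degree = weighted_degree,
    eigenvector = eigenvector_centrality,
    betweenness = weighted_betweenness,
    abort(sprintf("unknown metric `%s`", metric))
  )
}

#' Node-metric uncertainty from replicate networks
#'
#' Evaluates a node metric on each replicate network (posterior draws from
#' [draw_posterior_networks()] or bootstrap replicates via
#' [as_replicate_networks()]) and summarises the per-node distribution with
#' an equal-tailed percentile interval. The point column is the metric on a
#' supplied point-estimate network, or the replicate median when none is
#' given.
#'
#' @param replicates A `replicate_networks` list (or plain list of symmetric
#'   weight matrices), length >= 2.
#' @param metric `"degree"`, `"eigenvector"` or `"betweenness"`.
#' @param level Interval mass, default 0.95.
#' @param point_network Optional N x N matrix on which the point estimate is
#'   evaluated (e.g. the posterior-mode or observed SRI network).
#' @return A `metric_distribution` tibble: `node`, `point`, `lower`,
#'   `upper`; the full replicate-by-node value matrix is kept in the
#'   `values` attribute.
#' @export
metric_uncertainty <- function(replicates,
                               metric = c("degree", "eigenvector", "betweenness"),
                               level = 0.95, point_network = NULL) {
  metric <- match.arg(metric)
  if (length(replicates) < 2L) abort("need at least 2 replicate networks")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  f <- metric_fun(metric)
  vals <- t(vapply(replicates, function(w) suppressWarnings(unname(f(w))),
                   numeric(nrow(replicates[[1L]]))))
  tail <- (1 - level) / 2
  qs <- apply(vals, 2L, quantile, probs = c(tail, 0.5, 1 - tail),
              names = FALSE, type = 7L)
  ids <- rownames(replicates[[1L]]) %||% sprintf("n%02d", seq_len(ncol(vals)))
  point <- if (is.null(point_network)) qs[2L, ]
           else suppressWarnings(unname(f(point_network)))
  tibble::new_tibble(
    tibble::tibble(node = ids, point = point, lower = qs[1L, ], upper = qs[3L, ]),
    metric = metric, level = level, n_replicates = nrow(vals), values = vals,
    class = "metric_distribution"
  )
}

#' Write per-node metric summaries to CSV
#'
#' @param md A `metric_distribution`.
#' @param path Output path.
#' @param method Optional method tag recorded in the file.
#' @return The path, invisibly.
#' @export
write_node_metrics <- function(md, path, method = NA_character_) {
  stopifnot(inherits(md, "metric_distribution"))
  out <- dplyr::mutate(tibble::as_tibble(md),
                       metric = attr(md, "metric"),
                       n_replicates = attr(md, "n_replicates"),
                       method = method)
  readr::write_csv(out, path)
  invisible(path)
}
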