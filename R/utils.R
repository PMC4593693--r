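#' @importFrom rlang .data abort warn
#' @importFrom stats rpois rbinom rbeta qbeta pbeta lbeta optim quantile cor var setNames
#' @importFrom utils combn
NULL

# Dyad bookkeeping: every edge table in the package enumerates unordered pairs
# i < j in row-major upper-triangle order, i.e. (1,2), (1,3), ..., (1,N),
# (2,3), ... This order is part of the seeded-RNG contract of the stochastic
# operations, so it must never change.
dyad_index <- function(n) {
  if (n < 2) abort("need at least 2 nodes to form a dyad")
  ij <- t(combn(n, 2L))
  tibble::tibble(i = ij[, 1L], j = ij[, 2L])
}

# Extract the upper-triangle dyad vector of a symmetric matrix, in dyad order.
dyad_vector <- function(m) {
  m[upper.tri(m)][order_upper_tri(nrow(m))]
}

# upper.tri() is column-major; map it to row-major (1,2),(1,3),... order.
order_upper_tri <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  order(ij[, "row"], ij[, "col"])
}

# Build a symmetric zero-diagonal matrix from a dyad vector in row-major order.
dyad_matrix <- function(x, n, node_ids = NULL) {
  m <- matrix(0, n, n)
  idx <- dyad_index(n)
  m[cbind(idx$i, idx$j)] <- x
  m[cbind(idx$j, idx$i)] <- x
  if (!is.null(node_ids)) dimnames(m) <- list(node_ids, node_ids)
  m
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# with seed = NULL the global stream is used (and advanced).
with_seed_or_global <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

node_ids_of <- function(x) attr(x, "node_ids", exact = TRUE)

new_edge_tbl <- function(df, node_ids, class, ...) {
  out <- tibble::new_tibble(df, node_ids = node_ids, ...,
                            class = c(class, "netcred_edges"))
  out
}

#' Convert an edge table to a symmetric adjacency matrix
#'
#' Edge tables in netcred (SRI networks, credible/confidence interval sets,
#' posterior parameter tables) carry one row per unordered dyad. This helper
#' rebuilds the symmetric N x N matrix for a chosen column, with node IDs as
#' dimnames and a zero diagonal.
#'
#' @param x An edge table produced by [sri()], [credible_interval()],
#'   [bootstrap_edge_interval()], [clopper_pearson_interval()] or
#'   [posterior_update()], or a `true_network`.
#' @param value Name of the column to spread into the matrix.
#' @return A symmetric numeric matrix.
#' @export
as_adjacency_matrix <- function(x, value = "weight") {
  UseMethod("as_adjacency_matrix")
}

#' @export
as_adjacency_matrix.netcred_edges <- function(x, value = "weight") {
  if (!value %in% names(x)) {
    for (alt in c("weight", "point", "d")) {
      if (alt %in% names(x)) { value <- alt; break }
    }
  }
  if (!value %in% names(x)) abort(sprintf("column `%s` not found", value))
  ids <- node_ids_of(x)
  n <- length(ids)
  pos <- function(v) match(v, ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[cbind(pos(x$node_i), pos(x$node_j))] <- x[[value]]
  m[cbind(pos(x$node_j), pos(x$node_i))] <- x[[value]]
  m
}
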