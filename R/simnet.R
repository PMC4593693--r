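#' Generate a ground-truth weighted social network
#'
#' Simulates a "real" association network against which inference methods can
#' be benchmarked. Each individual receives a gregariousness score drawn from
#' Poisson(`poisson_rate`) plus a small offset (so no individual has score
#' zero), normalised by the largest score in the network so the most
#' gregarious individual has gregariousness 1. When `cliques = TRUE` each
#' individual is assigned independently and uniformly to one of `n_cliques`
#' communities; the true association probability of a dyad is then
#'
#'   weight(i, j) = g_i * g_j * p,
#'
#' where `p` is `p_within` for same-clique dyads and `p_between` otherwise.
#' Without cliques a single baseline probability `p_nocliques` is used. The
#' weight is the per-sampling-period probability that the dyad is observed
#' together, i.e. the association rate the downstream estimators target.
#'
#' Randomness is consumed in a fixed order (gregariousness scores for nodes
#' 1..N, then clique labels for nodes 1..N), so results are bit-reproducible
#' for a given seed.
#'
#' @param n_nodes Number of individuals (>= 2).
#' @param cliques Whether to impose community block structure.
#' @param n_cliques Number of communities (default 5).
#' @param poisson_rate Mean of the Poisson gregariousness draw (default 3).
#' @param gregariousness_offset Additive offset avoiding zero scores
#'   (default 0.05).
#' @param p_within,p_between Within-/between-clique association probabilities
#'   (defaults 0.9 and 0.1).
#' @param p_nocliques Baseline association probability when `cliques = FALSE`
#'   (default 0.5).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A `true_network`: list with `nodes` (tibble of `id`,
#'   `gregariousness` and, with cliques, `clique`) and `weights` (symmetric
#'   matrix of true association probabilities, zero diagonal).
#' @examples
#' net <- generate_true_network(15, seed = 1)
#' tidy(net)
#' @export
generate_true_network <- function(n_nodes,
                                  cliques = TRUE,
                                  n_cliques = 5L,
                                  poisson_rate = 3,
                                  gregariousness_offset = 0.05,
                                  p_within = 0.9,
                                  p_between = 0.1,
                                  p_nocliques = 0.5,
                                  seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  n_cliques <- check_count(n_cliques, "n_cliques", min = 1L)
  if (poisson_rate <= 0) abort("`poisson_rate` must be positive")
  if (gregariousness_offset <= 0) abort("`gregariousness_offset` must be positive")
  check_probability(p_within, "p_within")
  check_probability(p_between, "p_between")
  check_probability(p_nocliques, "p_nocliques")

  with_seed_or_global(seed, {
    score <- rpois(n_nodes, poisson_rate) + gregariousness_offset
    clique <- if (cliques) sample.int(n_cliques, n_nodes, replace = TRUE) else NULL
    greg <- score / max(score)
    ids <- sprintf("n%02d", seq_len(n_nodes))
    p <- if (cliques) {
      ifelse(outer(clique, clique, `==`), p_within, p_between)
    } else {
      matrix(p_nocliques, n_nodes, n_nodes)
    }
    w <- outer(greg, greg) * p
    diag(w) <- 0
    dimnames(w) <- list(ids, ids)
    nodes <- tibble::tibble(id = ids, gregariousness = greg)
    if (cliques) nodes$clique <- clique
    structure(
      list(nodes = nodes, weights = w),
      cliques = cliques,
      class = "true_network"
    )
  })
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf("<true_network: %d nodes, %d dyads%s>\n",
              nrow(x$nodes), nrow(x$nodes) * (nrow(x$nodes) - 1L) / 2L,
              if (isTRUE(attr(x, "cliques"))) ", clique-structured" else ""))
  print(x$nodes, ...)
  invisible(x)
}

#' @rdname generate_true_network
#' @param x A `true_network`.
#' @param ... Unused.
#' @method tidy true_network
#' @export
tidy.true_network <- function(x, ...) {
  ids <- x$nodes$id
  idx <- dyad_index(length(ids))
  out <- tibble::tibble(
    node_i = ids[idx$i],
    node_j = ids[idx$j],
    weight = x$weights[cbind(idx$i, idx$j)]
  )
  if (!is.null(x$nodes$clique)) {
    out$same_clique <- x$nodes$clique[idx$i] == x$nodes$clique[idx$j]
  }
  new_edge_tbl(out, ids, "true_edges")
}

#' @export
as_adjacency_matrix.true_network <- function(x, value = "weight") x$weights

#' Draw binary sampling periods from a true network
#'
#' Simulates `n_periods` observation rounds of the whole network. In each
#' period every dyad is independently recorded together (1) with probability
#' equal to its true edge weight, or apart (0). Every dyad is sampled in
#' every period, so the per-dyad sampling count equals `n_periods`.
#'
#' Randomness is consumed dyad by dyad in row-major i < j order, all periods
#' of a dyad consecutively, so results are bit-reproducible for a given seed.
#'
#' @param net A `true_network`.
#' @param n_periods Number of sampling periods S (>= 1).
#' @param seed Optional integer seed.
#' @return A `sampling_periods` object: `together` is an S x D binary matrix
#'   (periods by dyads, columns in dyad order), plus node IDs.
#' @examples
#' net <- generate_true_network(5, seed = 1)
#' obs <- sample_observations(net, 20, seed = 2)
#' tidy(obs)
#' @export
sample_observations <- function(net, n_periods, seed = NULL) {
  stopifnot(inherits(net, "true_network"))
  n_periods <- check_count(n_periods, "n_periods", min = 1L)
  w <- net$weights
  n <- nrow(w)
  idx <- dyad_index(n)
  theta <- w[cbind(idx$i, idx$j)]
  together <- with_seed_or_global(seed, {
    vapply(theta, function(p) rbinom(n_periods, 1L, p), integer(n_periods))
  })
  if (n_periods == 1L) together <- matrix(together, nrow = 1L)
  structure(
    list(together = together, node_ids = net$nodes$id, n_periods = n_periods),
    class = "sampling_periods"
  )
}

#' @export
print.sampling_periods <- function(x, ...) {
  cat(sprintf("<sampling_periods: %d periods x %d dyads (%d nodes)>\n",
              x$n_periods, ncol(x$together), length(x$node_ids)))
  invisible(x)
}

#' @rdname sample_observations
#' @param x A `sampling_periods` object.
#' @param ... Unused.
#' @return `tidy()` returns a long tibble with one row per period and dyad:
#'   `period`, `node_i`, `node_j`, `together`.
#' @method tidy sampling_periods
#' @export
tidy.sampling_periods <- function(x, ...) {
  idx <- dyad_index(length(x$node_ids))
  tibble::tibble(
    period = rep(seq_len(x$n_periods), times = nrow(idx)),
    node_i = rep(x$node_ids[idx$i], each = x$n_periods),
    node_j = rep(x$node_ids[idx$j], each = x$n_periods),
    together = as.integer(x$together[cbind(
      rep(seq_len(x$n_periods), times = nrow(idx)),
      rep(seq_len(nrow(idx)), each = x$n_periods)
    )])
  )
}

#' Write simulation objects to CSV
#'
#' `write_adjacency()` writes any edge table or network as a square adjacency
#' matrix CSV with node IDs as header row and first column.
#' `write_sampling_periods()` writes long-format observations
#' (`period, node_i, node_j, together`).
#'
#' @param x Object to write.
#' @param path Output file path.
#' @param value Column spread into the adjacency matrix (see
#'   [as_adjacency_matrix()]).
#' @return The path, invisibly.
#' @export
write_adjacency <- function(x, path, value = "weight") {
  m <- as_adjacency_matrix(x, value = value)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
write_sampling_periods <- function(x, path) {
  stopifnot(inherits(x, "sampling_periods"))
  readr::write_csv(tidy(x), path)
  invisible(path)
}
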