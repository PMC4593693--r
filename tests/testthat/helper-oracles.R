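# Independent oracles and small fixture builders used across the suite.

toy_counts <- function(d, s, ids = NULL) {
  n <- ceiling((1 + sqrt(1 + 8 * length(d))) / 2)
  if (is.null(ids)) ids <- LETTERS[seq_len(n)]
  ij <- t(combn(length(ids), 2))[seq_along(d), , drop = FALSE]
  dyad_counts(data.frame(node_i = ids[ij[, 1]], node_j = ids[ij[, 2]],
                         d = d, s = s))
}

# Brute-force betweenness: enumerate every simple path between each pair,
# keep the shortest under lengths 1/weight, and split the pair's unit of
# credit equally among the tied shortest paths' interior vertices.
brute_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  bw <- numeric(n)
  paths_between <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) { out[[length(out) + 1]] <<- path; return() }
      for (nxt in seq_len(n)) {
        if (w[last, nxt] > 0 && !(nxt %in% path)) walk(c(path, nxt))
      }
    }
    walk(from)
    out
  }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ps <- paths_between(a, b)
    if (!length(ps)) next
    lens <- vapply(ps, function(p) {
      sum(1 / w[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    best <- min(lens)
    short <- ps[lens <= best + tol]
    for (p in short) {
      inner <- p[-c(1, length(p))]
      if (length(inner)) bw[inner] <- bw[inner] + 1 / length(short)
    }
  }
  bw
}

# Grid-search maximiser of the beta-binomial marginal likelihood, the
# independent check on the simplex prior fit.
grid_prior_fit <- function(d, s, a_grid, b_grid) {
  ll <- function(a, b) sum(lbeta(a + d, b + s - d) - lbeta(a, b))
  vals <- outer(a_grid, b_grid, Vectorize(ll))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  c(a = a_grid[best[1]], b = b_grid[best[2]], ll = max(vals))
}

# Bisection inversion of the regularized incomplete beta function.
bisect_beta_quantile <- function(p, a, b, tol = 1e-12) {
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pbeta(mid, a, b) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Bisection inversion of exact binomial tail probabilities for the
# Clopper-Pearson bounds.
bisect_cp_bounds <- function(d, s, level = 0.95, tol = 1e-10) {
  al <- (1 - level) / 2
  lower <- if (d == 0) 0 else {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {            # find p: P(X >= d | p) = al
      mid <- (lo + hi) / 2
      if (1 - pbinom(d - 1, s, mid) < al) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  upper <- if (d == s) 1 else {
    lo <- 0; hi <- 1
    while (hi - lo > tol) {            # find p: P(X <= d | p) = al
      mid <- (lo + hi) / 2
      if (pbinom(d, s, mid) > al) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  c(lower = lower, upper = upper)
}

# Spearman correlation from first principles: average ranks, then the
# product-moment formula.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Deterministic two-node network with a chosen single edge weight.
two_node_net <- function(weight) {
  w <- matrix(c(0, weight, weight, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  nodes <- tibble::tibble(id = c("A", "B"), gregariousness = c(1, 1))
  structure(list(nodes = nodes, weights = w), cliques = FALSE,
            class = "true_network")
}

periods_from_matrix <- function(m, ids) {
  structure(list(together = m, node_ids = ids, n_periods = nrow(m)),
            class = "sampling_periods")
}
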