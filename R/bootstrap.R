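#' Bootstrap replicate SRI networks
#'
#' Resamples whole sampling units — periods for `sampling_periods` input,
#' observed groups (rows) for group-by-individual input — uniformly with
#' replacement to the original size, and recomputes the full SRI network for
#' each resample. Resampling whole units keeps each snapshot of the network
#' together, which is essential for the comparator's validity; individual
#' dyad observations are never resampled independently.
#'
#' @param obs A `sampling_periods` object or a K x N binary GBI matrix.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @return A `bootstrap_ensemble`: `weights` is an `n_boot` x D matrix of
#'   replicate SRI values (dyads in row-major i < j order), `observed` the
#'   SRI network of the original data.
#' @examples
#' net <- generate_true_network(5, seed = 1)
#' obs <- sample_observations(net, 20, seed = 2)
#' ens <- bootstrap_networks(obs, n_boot = 100, seed = 3)
#' bootstrap_edge_interval(ens)
#' @export
bootstrap_networks <- function(obs, n_boot = 100L, seed = NULL) {
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  if (inherits(obs, "sampling_periods")) {
    S <- obs$n_periods
    counts_of <- function(rows) {
      counts_from_periods(structure(
        list(together = obs$together[rows, , drop = FALSE],
             node_ids = obs$node_ids, n_periods = length(rows)),
        class = "sampling_periods"))
    }
    observed <- sri(counts_from_periods(obs))
  } else {
    m <- as.matrix(obs)
    S <- nrow(m)
    if (is.null(S) || S < 1L) abort("need at least one sampling unit")
    counts_of <- function(rows) counts_from_gbi(m[rows, , drop = FALSE])
    observed <- sri(counts_from_gbi(m))
  }
  if (S < 1L) abort("need at least one sampling unit")
  n_dyads <- nrow(observed)
  weights <- with_seed_or_global(seed, {
    res <- vapply(seq_len(n_boot), function(b) {
      rows <- sample.int(S, S, replace = TRUE)
      sri(counts_of(rows))$weight
    }, numeric(n_dyads))
    # vapply drops to a vector when the network has a single dyad
    if (is.matrix(res)) t(res) else matrix(res, ncol = n_dyads)
  })
  structure(
    list(weights = weights, observed = observed,
         node_ids = node_ids_of(observed), n_boot = n_boot, n_units = S),
    class = "bootstrap_ensemble"
  )
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble: %d replicates of %d dyads from %d sampling units>\n",
              x$n_boot, ncol(x$weights), x$n_units))
  invisible(x)
}

#' Percentile bootstrap intervals on SRI edge weights
#'
#' Per dyad, the `(1 - level)/2` and `(1 + level)/2` percentiles of the
#' replicate SRI values (linear interpolation between order statistics,
#' `stats::quantile()` type 7). The point estimate is the plain SRI on the
#' original data. With a single sampling unit every resample reproduces the
#' observed data, so all intervals have width exactly zero — the known
#' degenerate behaviour of the bootstrap at minimal sample size.
#'
#' @param ens A `bootstrap_ensemble`.
#' @param level Interval mass, default 0.95.
#' @return An `edge_estimates` tibble (method `"sri_bootstrap"`).
#' @export
bootstrap_edge_interval <- function(ens, level = 0.95) {
  stopifnot(inherits(ens, "bootstrap_ensemble"))
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  tail <- (1 - level) / 2
  qs <- apply(ens$weights, 2L, quantile, probs = c(tail, 1 - tail),
              names = FALSE, type = 7L)
  new_edge_tbl(
    tibble::tibble(
      node_i = ens$observed$node_i, node_j = ens$observed$node_j,
      point = ens$observed$weight,
      lower = qs[1L, ], upper = qs[2L, ],
      unsampled = ens$observed$unsampled
    ),
    ens$node_ids, "edge_estimates",
    method = "sri_bootstrap", level = level,
    quantile_rule = "type 7 (linear interpolation between order statistics)"
  )
}

#' Clopper-Pearson exact binomial intervals on edge weights
#'
#' The exact small-sample confidence interval on a binomial proportion,
#' obtained by inverting the binomial tail probabilities; in beta-quantile
#' form the bounds for a dyad with counts (d, s) are
#' `qbeta((1-level)/2; d, s-d+1)` (0 when d = 0) and
#' `qbeta((1+level)/2; d+1, s-d)` (1 when d = s). These intervals are exact
#' but conservative: realised coverage is at least the nominal level.
#' Unsampled dyads (`s = 0`) get the uninformative interval (0, 1).
#'
#' @param counts A `dyad_counts` tibble.
#' @param level Confidence level, default 0.95.
#' @return An `edge_estimates` tibble (method `"clopper_pearson"`, point
#'   estimate `d/s`).
#' @export
clopper_pearson_interval <- function(counts, level = 0.95) {
  validate_counts(counts)
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  tail <- (1 - level) / 2
  d <- counts$d; s <- counts$s
  lower <- ifelse(d == 0L, 0, qbeta(tail, d, s - d + 1))
  upper <- ifelse(d == s, 1, qbeta(1 - tail, d + 1, s - d))
  lower[s == 0L] <- 0
  upper[s == 0L] <- 1
  new_edge_tbl(
    tibble::tibble(
      node_i = counts$node_i, node_j = counts$node_j,
      point = ifelse(s > 0L, d / pmax(s, 1L), 0),
      lower = lower, upper = upper,
      unsampled = s == 0L
    ),
    node_ids_of(counts), "edge_estimates",
    method = "clopper_pearson", level = level
  )
}

#' Replicate weight matrices from an ensemble
#'
#' Converts a `bootstrap_ensemble` to the list-of-matrices form consumed by
#' [metric_uncertainty()] (the form [draw_posterior_networks()] already
#' returns).
#'
#' @param x A `bootstrap_ensemble`.
#' @return A `replicate_networks` list of symmetric weight matrices.
#' @export
as_replicate_networks <- function(x) {
  stopifnot(inherits(x, "bootstrap_ensemble"))
  n <- length(x$node_ids)
  nets <- lapply(seq_len(x$n_boot), function(b) {
    dyad_matrix(x$weights[b, ], n, x$node_ids)
  })
  structure(nets, class = "replicate_networks", node_ids = x$node_ids)
}

#' Estimate edge weights and intervals with a chosen method
#'
#' One-call front end shared by the evaluation framework and the
#' command-line interface: reduces observations to dyadic counts and applies
#' one of the three estimators.
#'
#' @param obs A `sampling_periods` object or GBI matrix.
#' @param method `"bayes"` (empirical-Bayes beta posterior),
#'   `"sri_bootstrap"` (percentile bootstrap of SRI networks) or
#'   `"clopper_pearson"` (exact binomial interval around the SRI).
#' @param level Interval mass / confidence level.
#' @param n_boot Bootstrap replicates (bootstrap method only).
#' @param prior Optional `beta_prior` to use instead of the empirical fit.
#' @param seed Optional integer seed (bootstrap method only).
#' @return An `edge_estimates` tibble.
#' @export
estimate_edges <- function(obs,
                           method = c("bayes", "sri_bootstrap", "clopper_pearson"),
                           level = 0.95, n_boot = 100L, prior = NULL,
                           seed = NULL) {
  method <- match.arg(method)
  counts <- if (inherits(obs, "dyad_counts")) obs
            else if (inherits(obs, "sampling_periods")) counts_from_periods(obs)
            else counts_from_gbi(obs)
  switch(method,
    bayes = {
      if (is.null(prior)) prior <- fit_empirical_prior(counts)
      credible_interval(posterior_update(counts, prior), level = level)
    },
    sri_bootstrap = {
      if (inherits(obs, "dyad_counts"))
        abort("the bootstrap needs the sampling units, not aggregated counts")
      bootstrap_edge_interval(bootstrap_networks(obs, n_boot = n_boot,
                                                 seed = seed), level = level)
    },
    clopper_pearson = clopper_pearson_interval(counts, level = level)
  )
}

#' Write an edge-estimate table to CSV
#'
#' One row per dyad with the producing method, level and quantile rule
#' recorded in a commented metadata header.
#'
#' @param est An `edge_estimates` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_estimates <- function(est, path) {
  stopifnot(inherits(est, "edge_estimates"))
  meta <- sprintf("# method: %s; level: %s; quantile_rule: %s",
                  attr(est, "method"), attr(est, "level"),
                  attr(est, "quantile_rule") %||% "beta quantiles (equal-tailed)")
  writeLines(meta, path)
  readr::write_csv(tibble::as_tibble(est), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
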