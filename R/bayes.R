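#' Fit an empirical-Bayes beta prior to dyadic counts
#'
#' Edge weights are modelled as draws from a common Beta(a, b) prior. The
#' prior parameters are fitted by type-II maximum likelihood: the unknown
#' edge weight of each dyad is integrated out, leaving the beta-binomial
#' marginal likelihood of the counts, and (a, b) maximise (up to binomial
#' coefficients, which do not depend on the parameters)
#'
#'   sum over sampled dyads of  lnB(a + d, b + s - d) - lnB(a, b),
#'
#' where B is the beta function. The optimisation runs over (ln a, ln b)
#' with a Nelder-Mead simplex from a method-of-moments start; fitted values
#' are clamped to `bounds`, with a warning when the optimum is attracted to
#' a boundary (e.g. all-zero or all-one data). Dyads with `s = 0` carry no
#' likelihood and are excluded.
#'
#' Using all observed data to set the prior is empirical Bayes — an
#' approximation to a full hierarchical model; a stricter alternative is to
#' fit the prior on a held-out subset of sampling units (see
#' [holdout_split()]).
#'
#' @param counts A `dyad_counts` tibble; at least 2 dyads with `s > 0`.
#' @param bounds Length-2 box constraint on both parameters
#'   (default `c(1e-3, 1e3)`).
#' @return A `beta_prior`: list with `a`, `b`, `log_marginal` (maximised
#'   objective), `n_dyads_used`, `boundary` flag.
#' @examples
#' net <- generate_true_network(15, seed = 1)
#' obs <- sample_observations(net, 20, seed = 2)
#' prior <- counts_from_periods(obs) |> fit_empirical_prior()
#' glance(prior)
#' @export
fit_empirical_prior <- function(counts, bounds = c(1e-3, 1e3)) {
  validate_counts(counts)
  keep <- counts$s > 0L
  if (sum(keep) < 2L)
    abort("need at least 2 dyads with s > 0 to fit a prior")
  d <- counts$d[keep]
  s <- counts$s[keep]

  obj <- function(lp) {
    a <- exp(lp[1L]); b <- exp(lp[2L])
    -sum(lbeta(a + d, b + s - d) - lbeta(a, b))
  }

  # method-of-moments start on the raw proportions
  p <- d / s
  m <- mean(p); v <- var(p)
  k <- if (is.finite(v) && v > 0 && v < m * (1 - m)) m * (1 - m) / v - 1 else 2
  start <- log(pmin(pmax(c(m * k, (1 - m) * k), bounds[1L]), bounds[2L]))

  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 5000L))
  ab <- exp(fit$par)
  boundary <- any(ab < bounds[1L]) || any(ab > bounds[2L])
  if (boundary) {
    warn(paste0("prior fit attracted to the parameter boundary ",
                "(data nearly all-zero or all-one); clamping to bounds"))
    ab <- pmin(pmax(ab, bounds[1L]), bounds[2L])
  }
  structure(
    list(a = ab[1L], b = ab[2L], log_marginal = -obj(log(ab)),
         n_dyads_used = sum(keep), boundary = boundary),
    class = "beta_prior"
  )
}

#' Construct a beta prior by hand
#'
#' @param a,b Positive shape parameters; `Beta(1, 1)` is the uniform prior.
#' @return A `beta_prior`.
#' @export
beta_prior <- function(a = 1, b = 1) {
  if (a <= 0 || b <= 0) abort("prior parameters must be positive")
  structure(list(a = a, b = b, log_marginal = NA_real_,
                 n_dyads_used = 0L, boundary = FALSE),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("<beta_prior: Beta(a = %.4g, b = %.4g)", x$a, x$b))
  if (is.finite(x$log_marginal))
    cat(sprintf(", log-marginal %.4g over %d dyads", x$log_marginal,
                x$n_dyads_used))
  cat(">\n")
  invisible(x)
}

#' @rdname fit_empirical_prior
#' @param x A `beta_prior`.
#' @param ... Unused.
#' @method glance beta_prior
#' @export
glance.beta_prior <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, log_marginal = x$log_marginal,
                 n_dyads_used = x$n_dyads_used, boundary = x$boundary)
}

#' Beta-binomial conjugate posterior for every dyad
#'
#' Updates the prior with the observed counts. The beta prior is conjugate
#' to the Bernoulli observation model, so the posterior of each edge weight
#' is Beta(alpha, beta) with `alpha = a + d` and `beta = b + (s - d)`. Dyads
#' with `s = 0` keep the bare prior and are flagged `unsampled`.
#'
#' @param counts A `dyad_counts` tibble.
#' @param prior A `beta_prior`, from [fit_empirical_prior()] or
#'   [beta_prior()].
#' @return A `posterior_network` tibble: `node_i`, `node_j`, `d`, `s`,
#'   `alpha`, `beta`, `unsampled`; the prior is carried as an attribute.
#' @examples
#' # a uniform prior updated with observations 1, 0, 1 gives Beta(3, 2)
#' toy <- dyad_counts(data.frame(node_i = "A", node_j = "B", d = 2, s = 3))
#' posterior_update(toy, beta_prior(1, 1))
#' @export
posterior_update <- function(counts, prior) {
  validate_counts(counts)
  stopifnot(inherits(prior, "beta_prior"))
  new_edge_tbl(
    dplyr::mutate(tibble::as_tibble(counts),
                  alpha = prior$a + .data$d,
                  beta = prior$b + (.data$s - .data$d),
                  unsampled = .data$s == 0L),
    node_ids_of(counts), "posterior_network",
    prior = prior,
    n_units = attr(counts, "n_units", exact = TRUE)
  )
}

#' Posterior point estimate: the mode of each edge's beta posterior
#'
#' The reported edge weight is the most probable value, i.e. the peak of the
#' posterior density: `(alpha - 1) / (alpha + beta - 2)` when both shape
#' parameters exceed 1, 0 when only `alpha <= 1`, and 1 when only
#' `beta <= 1`. When both are at most 1 the density has no interior peak and
#' the posterior mean `alpha / (alpha + beta)` is used as a documented
#' fallback (with a warning).
#'
#' @param post A `posterior_network` from [posterior_update()].
#' @return The input tibble with a `point` column added.
#' @export
posterior_point <- function(post) {
  stopifnot(inherits(post, "posterior_network"))
  a <- post$alpha; b <- post$beta
  pt <- ifelse(a > 1 & b > 1, (a - 1) / (a + b - 2),
        ifelse(a <= 1 & b > 1, 0,
        ifelse(b <= 1 & a > 1, 1, a / (a + b))))
  if (any(a <= 1 & b <= 1))
    warn("posterior density has no interior mode for some dyads; using the posterior mean there")
  post$point <- pt
  post
}

#' Equal-tailed credible intervals on edge weights
#'
#' Extracts the central interval containing `level` of each edge's posterior
#' probability mass: beta quantiles at `(1 - level)/2` and `(1 + level)/2`.
#' The point estimate is the posterior mode (see [posterior_point()]).
#'
#' @param post A `posterior_network`.
#' @param level Interval mass, default 0.95.
#' @return An `edge_estimates` tibble: `node_i`, `node_j`, `point`,
#'   `lower`, `upper`, `unsampled`; attributes `method = "bayes"` and
#'   `level`.
#' @export
credible_interval <- function(post, level = 0.95) {
  stopifnot(inherits(post, "posterior_network"))
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1)")
  tail <- (1 - level) / 2
  pt <- suppressWarnings(posterior_point(post))
  new_edge_tbl(
    tibble::tibble(
      node_i = post$node_i, node_j = post$node_j,
      point = pt$point,
      lower = qbeta(tail, post$alpha, post$beta),
      upper = qbeta(1 - tail, post$alpha, post$beta),
      unsampled = post$unsampled
    ),
    node_ids_of(post), "edge_estimates",
    method = "bayes", level = level
  )
}

#' Draw replicate networks from the posterior
#'
#' Samples `n_draws` full networks by drawing each edge weight independently
#' from its posterior beta distribution (dyads in row-major i < j order
#' within each draw, draws consecutive), mirroring to symmetry with a zero
#' diagonal. These replicate networks propagate edge-weight uncertainty to
#' node-level metrics via [metric_uncertainty()].
#'
#' @param post A `posterior_network`.
#' @param n_draws Number of replicate networks (default 100).
#' @param seed Optional integer seed.
#' @return A `replicate_networks` list of symmetric weight matrices.
#' @export
draw_posterior_networks <- function(post, n_draws = 100L, seed = NULL) {
  stopifnot(inherits(post, "posterior_network"))
  n_draws <- check_count(n_draws, "n_draws", min = 1L)
  ids <- node_ids_of(post)
  n <- length(ids)
  nd <- nrow(post)
  nets <- with_seed_or_global(seed, {
    lapply(seq_len(n_draws), function(k) {
      dyad_matrix(rbeta(nd, post$alpha, post$beta), n, ids)
    })
  })
  structure(nets, class = "replicate_networks", node_ids = ids)
}

#' Split sampling units into a prior-fitting and an updating subset
#'
#' Supports the stricter variant of prior construction in which the beta
#' prior is fitted on a held-out fraction of the sampling units and the
#' posterior is updated only with the remainder, keeping prior and
#' likelihood independent.
#'
#' @param obs A `sampling_periods` object.
#' @param fraction Fraction of periods used for the prior (default 0.5).
#' @param seed Optional integer seed for the random split.
#' @return A list with `prior_obs` and `update_obs`, both `sampling_periods`.
#' @export
holdout_split <- function(obs, fraction = 0.5, seed = NULL) {
  stopifnot(inherits(obs, "sampling_periods"))
  check_probability(fraction, "fraction")
  S <- obs$n_periods
  n_prior <- max(1L, min(S - 1L, round(fraction * S)))
  pick <- with_seed_or_global(seed, sort(sample.int(S, n_prior)))
  subset_periods <- function(rows) {
    structure(list(together = obs$together[rows, , drop = FALSE],
                   node_ids = obs$node_ids, n_periods = length(rows)),
              class = "sampling_periods")
  }
  list(prior_obs = subset_periods(pick),
       update_obs = subset_periods(setdiff(seq_len(S), pick)))
}

#' Write fitted prior parameters as JSON
#'
#' @param prior A `beta_prior`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "beta_prior"))
  jsonlite::write_json(unclass(prior), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
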