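#' Edge-level accuracy measures against a known truth
#'
#' `mean_absolute_error()` is the mean of |estimate - truth| over unordered
#' dyads; `rank_correlation()` is the Spearman correlation (average ranks
#' for ties) between estimated and true values, capturing relative rather
#' than absolute accuracy. A constant input vector has no rank ordering, so
#' the correlation is undefined and returned as `NA` with a warning.
#'
#' @param estimate,truth Symmetric matrices of equal size, edge tables
#'   ([sri()] / [credible_interval()] output, `point`/`weight` column), or —
#'   for `rank_correlation()` — plain numeric vectors of equal length >= 3.
#' @return A single number.
#' @examples
#' mean_absolute_error(matrix(0.6, 3, 3) - diag(0.6, 3), matrix(0.5, 3, 3) - diag(0.5, 3))
#' @export
mean_absolute_error <- function(estimate, truth) {
  e <- edgewise_values(estimate)
  t_ <- edgewise_values(truth)
  if (length(e) != length(t_)) abort("estimate and truth have different sizes")
  mean(abs(e - t_))
}

#' @rdname mean_absolute_error
#' @export
rank_correlation <- function(estimate, truth) {
  e <- edgewise_values(estimate)
  t_ <- edgewise_values(truth)
  if (length(e) != length(t_)) abort("estimate and truth have different sizes")
  if (length(e) < 3L) abort("need at least 3 values for a rank correlation")
  if (length(unique(e)) == 1L || length(unique(t_)) == 1L) {
    warn("rank correlation undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  cor(e, t_, method = "spearman")
}

edgewise_values <- function(x) {
  if (inherits(x, "true_network")) return(dyad_vector(x$weights))
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) abort("matrix input must be square")
    return(dyad_vector(x))
  }
  if (is.data.frame(x)) {
    for (col in c("point", "weight")) if (col %in% names(x)) return(x[[col]])
    abort("edge table lacks a `point` or `weight` column")
  }
  as.numeric(x)
}

#' Interval reliability: false-positive and false-negative rates
#'
#' A false positive is a quantity whose true value falls strictly below the
#' estimated 95% interval (the interval overstates it); a false negative is
#' one whose true value falls strictly above it. Calibrated equal-tailed
#' 95% intervals put each rate at approximately 2.5%.
#'
#' @param est An `edge_estimates` or `metric_distribution` table (columns
#'   `lower` and `upper`).
#' @param truth True values aligned with the rows of `est`: a numeric
#'   vector, a symmetric matrix, or a `true_network`.
#' @return A one-row tibble with `fp_rate`, `fn_rate`, `n`.
#' @export
interval_coverage <- function(est, truth) {
  if (!all(c("lower", "upper") %in% names(est)))
    abort("`est` must carry `lower` and `upper` columns")
  t_ <- if (inherits(est, "metric_distribution")) {
    if (inherits(truth, "true_network") || is.matrix(truth))
      abort("metric-level coverage needs a per-node truth vector")
    as.numeric(truth)
  } else {
    edgewise_values(truth)
  }
  if (length(t_) != nrow(est)) abort("truth not aligned with `est`")
  tibble::tibble(
    fp_rate = mean(t_ < est$lower),
    fn_rate = mean(t_ > est$upper),
    n = nrow(est)
  )
}

#' Simulation study of estimator accuracy and interval reliability
#'
#' Runs the full benchmarking loop: for each replicate, generate a true
#' network, draw S sampling periods, estimate edge weights with each
#' method, and score edge-level accuracy (mean absolute error, Spearman
#' rank correlation) and interval reliability (false-positive/negative
#' rates). With `levels` including `"degree"`, node-strength uncertainty is
#' propagated through 100 replicate networks (posterior draws for the
#' Bayesian method, bootstrap resamples for b-SRI; the Clopper-Pearson
#' method has no replicate-network ensemble and is scored at the edge level
#' only).
#'
#' @param n_networks Replicate true networks per cell (default 100).
#' @param s_grid Sampling efforts S to evaluate.
#' @param n_nodes,cliques,... Generator settings passed to
#'   [generate_true_network()].
#' @param methods Estimators to include.
#' @param levels `"edge"` and/or `"degree"`.
#' @param n_replicates Replicate networks per ensemble for node-level
#'   uncertainty (default 100).
#' @param level Interval mass (default 0.95).
#' @param seed Integer seed; each replicate uses an independent substream.
#' @return A tibble with one row per network x S x method x level:
#'   `network`, `s`, `method`, `eval_level`, `mean_error`,
#'   `rank_correlation`, `fp_rate`, `fn_rate`. Summarise across replicates
#'   with [summarize_study()].
#' @export
run_simulation_study <- function(n_networks = 100L,
                                 s_grid = c(10L, 20L, 50L),
                                 n_nodes = 15L,
                                 cliques = TRUE,
                                 methods = c("bayes", "sri_bootstrap",
                                             "clopper_pearson"),
                                 levels = "edge",
                                 n_replicates = 100L,
                                 level = 0.95,
                                 seed = 1L,
                                 ...) {
  n_networks <- check_count(n_networks, "n_networks", min = 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  levels <- match.arg(levels, c("edge", "degree"), several.ok = TRUE)
  cells <- purrr::map(seq_len(n_networks), function(r) {
    net <- generate_true_network(n_nodes, cliques = cliques,
                                 seed = seed + 1000L * r, ...)
    purrr::map(s_grid, function(S) {
      obs <- sample_observations(net, S, seed = seed + 1000L * r + S)
      counts <- counts_from_periods(obs)
      purrr::map(methods, function(m) {
        score_method(net, obs, counts, m, S, r, levels, n_replicates, level,
                     seed + 1000L * r + S)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(cells)
}

score_method <- function(net, obs, counts, method, S, r, levels,
                         n_replicates, level, seed) {
  est <- suppressWarnings(
    estimate_edges(obs, method = method, level = level,
                   n_boot = n_replicates, seed = seed)
  )
  truth_vec <- dyad_vector(net$weights)
  cov <- interval_coverage(est, truth_vec)
  out <- tibble::tibble(
    network = r, s = S, method = method, eval_level = "edge",
    mean_error = mean_absolute_error(est, truth_vec),
    rank_correlation = suppressWarnings(rank_correlation(est, truth_vec)),
    fp_rate = cov$fp_rate, fn_rate = cov$fn_rate
  )
  if ("degree" %in% levels && method != "clopper_pearson") {
    reps <- if (method == "bayes") {
      prior <- suppressWarnings(fit_empirical_prior(counts))
      draw_posterior_networks(posterior_update(counts, prior),
                              n_draws = n_replicates, seed = seed + 1L)
    } else {
      as_replicate_networks(
        bootstrap_networks(obs, n_boot = n_replicates, seed = seed)
      )
    }
    md <- metric_uncertainty(reps, "degree", level = level,
                             point_network = as_adjacency_matrix(est, "point"))
    truth_deg <- weighted_degree(net$weights)
    covd <- interval_coverage(md, truth_deg)
    out <- dplyr::bind_rows(out, tibble::tibble(
      network = r, s = S, method = method, eval_level = "degree",
      mean_error = mean(abs(md$point - truth_deg)),
      rank_correlation = suppressWarnings(
        rank_correlation(md$point, unname(truth_deg))),
      fp_rate = covd$fp_rate, fn_rate = covd$fn_rate
    ))
  }
  out
}

#' Summarise a simulation study across replicate networks
#'
#' Median and central 95% range of each score over replicate networks, per
#' sampling effort, method and evaluation level.
#'
#' @param results Output of [run_simulation_study()].
#' @return A tibble with `median`, `q2.5`, `q97.5` per score.
#' @export
summarize_study <- function(results) {
  results |>
    tidyr::pivot_longer(cols = c("mean_error", "rank_correlation",
                                 "fp_rate", "fn_rate"),
                        names_to = "score", values_to = "value") |>
    dplyr::group_by(.data$s, .data$method, .data$eval_level, .data$score) |>
    dplyr::summarise(
      median = stats::median(.data$value, na.rm = TRUE),
      q2.5 = quantile(.data$value, 0.025, na.rm = TRUE, names = FALSE),
      q97.5 = quantile(.data$value, 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}

#' Reliability of an observed network under subsampling
#'
#' Asks whether the available observations already pin down the network:
#' for increasing sampling effort S along a grid, the first S sampling
#' units (cumulative-prefix mode, the default) or a seeded random subset of
#' size S are re-analysed with the chosen method, recording each dyad's
#' point estimate and 95% bounds plus the mean weighted degree. If the
#' tracked quantity has stabilised by the full sample size, the observed
#' network is likely a reliable estimate of the real one; if it is still
#' drifting, more data are needed.
#'
#' For the Bayesian method the curve includes an S = 0 point at which every
#' dyad carries the bare fitted prior — the uncertainty before any
#' dyad-specific data — so the characteristic funnel starts from the full
#' prior interval. Subsampling is without replacement.
#'
#' @param obs A `sampling_periods` object or GBI matrix.
#' @param grid_step Grid increment in sampling units (e.g. 20 observed
#'   groups).
#' @param method Estimator used at each grid point.
#' @param mode `"cumulative"` (prefix in observation order) or `"random"`
#'   (seeded random subset per grid point).
#' @param level Interval mass (default 0.95).
#' @param n_boot Bootstrap/posterior replicates per grid point.
#' @param seed Optional integer seed.
#' @return A `reliability_curve`: list with `edges` (tibble: `s`, `node_i`,
#'   `node_j`, `point`, `lower`, `upper`) and `mean_degree` (tibble: `s`,
#'   `point`, `lower`, `upper`; interval `NA` for Clopper-Pearson, which has
#'   no replicate ensemble).
#' @export
subsample_stability <- function(obs,
                                grid_step = 20L,
                                method = c("bayes", "sri_bootstrap",
                                           "clopper_pearson"),
                                mode = c("cumulative", "random"),
                                level = 0.95, n_boot = 100L, seed = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  grid_step <- check_count(grid_step, "grid_step", min = 1L)
  units <- if (inherits(obs, "sampling_periods")) obs$n_periods else nrow(as.matrix(obs))
  if (grid_step > units) {
    warn("grid step exceeds the number of sampling units; single-point curve")
    grid <- units
  } else {
    grid <- unique(c(seq(grid_step, units, by = grid_step), units))
  }
  if (method == "bayes") grid <- c(0L, grid)

  take <- function(S, k) {
    rows <- if (mode == "cumulative") seq_len(S)
            else with_seed_or_global(if (is.null(seed)) NULL else seed + k,
                                     sort(sample.int(units, S)))
    subset_units(obs, rows)
  }
  full_counts <- if (inherits(obs, "sampling_periods")) counts_from_periods(obs)
                 else counts_from_gbi(as.matrix(obs))
  prior <- if (method == "bayes") suppressWarnings(fit_empirical_prior(full_counts))
           else NULL

  pieces <- purrr::imap(grid, function(S, k) {
    if (S == 0L) {
      post0 <- posterior_update(zero_counts(full_counts), prior)
      est <- credible_interval(post0, level = level)
      reps <- draw_posterior_networks(post0, n_draws = n_boot,
                                      seed = if (is.null(seed)) NULL else seed + k)
    } else {
      sub <- take(S, k)
      est <- suppressWarnings(
        estimate_edges(sub, method = method, level = level, n_boot = n_boot,
                       prior = prior,
                       seed = if (is.null(seed)) NULL else seed + k))
      reps <- switch(method,
        bayes = {
          cts <- if (inherits(sub, "sampling_periods")) counts_from_periods(sub)
                 else counts_from_gbi(as.matrix(sub))
          draw_posterior_networks(posterior_update(cts, prior),
                                  n_draws = n_boot,
                                  seed = if (is.null(seed)) NULL else seed + k)
        },
        sri_bootstrap = as_replicate_networks(
          bootstrap_networks(sub, n_boot = n_boot,
                             seed = if (is.null(seed)) NULL else seed + k)),
        clopper_pearson = NULL
      )
    }
    pt_mat <- as_adjacency_matrix(est, "point")
    md <- if (is.null(reps)) {
      tibble::tibble(s = S, point = mean(weighted_degree(pt_mat)),
                     lower = NA_real_, upper = NA_real_)
    } else {
      mean_deg <- vapply(reps, function(w) mean(weighted_degree(w)), numeric(1L))
      tail <- (1 - level) / 2
      tibble::tibble(s = S, point = mean(weighted_degree(pt_mat)),
                     lower = quantile(mean_deg, tail, names = FALSE),
                     upper = quantile(mean_deg, 1 - tail, names = FALSE))
    }
    list(edges = dplyr::mutate(tibble::as_tibble(est), s = S,
                               .before = 1L),
         mean_degree = md)
  })
  structure(
    list(
      edges = purrr::list_rbind(purrr::map(pieces, "edges")),
      mean_degree = purrr::list_rbind(purrr::map(pieces, "mean_degree")),
      method = method, mode = mode, level = level, grid = grid
    ),
    class = "reliability_curve"
  )
}

subset_units <- function(obs, rows) {
  if (inherits(obs, "sampling_periods")) {
    structure(list(together = obs$together[rows, , drop = FALSE],
                   node_ids = obs$node_ids, n_periods = length(rows)),
              class = "sampling_periods")
  } else {
    as.matrix(obs)[rows, , drop = FALSE]
  }
}

zero_counts <- function(counts) {
  out <- dplyr::mutate(tibble::as_tibble(counts), d = 0L, s = 0L)
  new_edge_tbl(out, node_ids_of(counts), "dyad_counts", n_units = 0L)
}

#' @export
print.reliability_curve <- function(x, ...) {
  cat(sprintf("<reliability_curve: method %s, %s subsampling, grid %s>\n",
              x$method, x$mode, paste(x$grid, collapse = ", ")))
  invisible(x)
}

#' Has a reliability curve stabilised?
#'
#' Reporting heuristic: the curve counts as stabilised when the intervals at
#' the final two grid points mutually overlap and the point estimates differ
#' by less than `tol` (relative). This flags whether collecting the last
#' increment of data still moved the estimate; it is a diagnostic, not a
#' test.
#'
#' @param curve A `reliability_curve`.
#' @param metric `"mean_degree"` (scalar curve) or `"edge"` (fraction of
#'   dyads stabilised).
#' @param tol Relative-change tolerance, default 0.05.
#' @return For `"mean_degree"`, a logical; for `"edge"`, the fraction of
#'   dyads meeting the criterion.
#' @export
is_stabilized <- function(curve, metric = c("mean_degree", "edge"),
                          tol = 0.05) {
  stopifnot(inherits(curve, "reliability_curve"))
  metric <- match.arg(metric)
  last2 <- utils::tail(sort(unique(curve$edges$s)), 2L)
  if (length(last2) < 2L) return(NA)
  stab <- function(p1, l1, u1, p2, l2, u2) {
    overlap <- l1 <= u2 & l2 <= u1
    close <- abs(p2 - p1) < tol * pmax(abs(p1), 1e-12)
    overlap & close
  }
  if (metric == "mean_degree") {
    md <- curve$mean_degree[curve$mean_degree$s %in% last2, ]
    if (any(is.na(md$lower))) {
      return(abs(diff(md$point)) < tol * max(abs(md$point[1L]), 1e-12))
    }
    stab(md$point[1L], md$lower[1L], md$upper[1L],
         md$point[2L], md$lower[2L], md$upper[2L])
  } else {
    e1 <- curve$edges[curve$edges$s == last2[1L], ]
    e2 <- curve$edges[curve$edges$s == last2[2L], ]
    mean(stab(e1$point, e1$lower, e1$upper, e2$point, e2$lower, e2$upper))
  }
}
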