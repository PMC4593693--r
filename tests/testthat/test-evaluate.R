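test_that("mean absolute edge error averages over unordered dyads", {
  a <- matrix(0.5, 4, 4); diag(a) <- 0
  b <- matrix(0.6, 4, 4); diag(b) <- 0
  expect_equal(mean_absolute_error(b, a), 0.1)
  expect_equal(mean_absolute_error(a, a), 0)

  set.seed(71)
  x <- matrix(0, 4, 4); x[upper.tri(x)] <- runif(6); x <- x + t(x)
  y <- matrix(0, 4, 4); y[upper.tri(y)] <- runif(6); y <- y + t(y)
  # direct enumeration over the 6 dyads
  manual <- mean(abs(x[upper.tri(x)] - y[upper.tri(y)]))
  expect_equal(mean_absolute_error(x, y), manual)
  expect_error(mean_absolute_error(a, matrix(0, 3, 3)), "different sizes")
})

test_that("rank correlation handles ties like the explicit rank formula", {
  expect_equal(rank_correlation(1:5, 2 * (1:5)), 1)
  expect_equal(rank_correlation(1:5, rev(1:5)), -1)
  x <- c(1, 2, 2, 3, 5, 5, 5)
  y <- c(2, 1, 4, 4, 6, 6, 9)
  expect_equal(rank_correlation(x, y), brute_spearman(x, y))
  expect_warning(r <- rank_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("interval coverage implements the strict FP/FN definitions", {
  est <- clopper_pearson_interval(toy_counts(d = c(0L, 1L, 2L), s = c(2L, 2L, 2L)))
  est$lower <- c(0.6, 0.1, 0.0)
  est$upper <- c(0.9, 0.4, 1.0)
  cov <- interval_coverage(est, c(0.5, 0.5, 0.5))
  expect_equal(cov$fp_rate, 1 / 3)   # truth below (0.6, 0.9)
  expect_equal(cov$fn_rate, 1 / 3)   # truth above (0.1, 0.4)

  est$lower <- rep(0, 3); est$upper <- rep(1, 3)
  cov2 <- interval_coverage(est, c(0.2, 0.5, 0.8))
  expect_equal(c(cov2$fp_rate, cov2$fn_rate), c(0, 0))
})

test_that("the study runner produces finite scores and handles degeneracy", {
  res <- run_simulation_study(n_networks = 1, s_grid = 10,
                              methods = c("bayes", "sri_bootstrap"),
                              levels = c("edge", "degree"),
                              n_replicates = 20, seed = 7)
  expect_equal(nrow(res), 4)   # 2 methods x 2 levels
  expect_true(all(is.finite(res$mean_error)))
  expect_true(all(res$fp_rate >= 0 & res$fp_rate + res$fn_rate <= 1))

  summ <- summarize_study(res)
  expect_true(all(c("median", "q2.5", "q97.5") %in% names(summ)))
})

test_that("rank correlation is flagged undefined on an equal-weight truth", {
  flat <- generate_true_network(6, cliques = FALSE, seed = 72)
  flat$weights[upper.tri(flat$weights)] <- 0.4
  flat$weights[lower.tri(flat$weights)] <- 0.4
  diag(flat$weights) <- 0
  obs <- sample_observations(flat, 10, seed = 73)
  est <- estimate_edges(obs, "clopper_pearson")
  expect_warning(r <- rank_correlation(dyad_vector(flat$weights), est$point),
                 "constant")
  expect_true(is.na(r))
  expect_true(is.finite(mean_absolute_error(est, flat$weights)))
})

test_that("edge error decreases with sampling effort for both methods", {
  res <- run_simulation_study(n_networks = 10, s_grid = c(5, 20, 50),
                              methods = c("bayes", "sri_bootstrap"),
                              n_replicates = 30, seed = 74)
  means <- res |>
    dplyr::group_by(method, s) |>
    dplyr::summarise(err = mean(mean_error), .groups = "drop") |>
    dplyr::arrange(method, s)
  for (m in unique(means$method)) {
    e <- means$err[means$method == m]
    expect_true(all(diff(e) < 0))
  }
})

test_that("subsampling curves funnel on well-sampled simulated input", {
  net <- generate_true_network(10, seed = 75)
  obs <- sample_observations(net, 200, seed = 76)
  curve <- subsample_stability(obs, grid_step = 20, method = "bayes",
                               n_boot = 30, seed = 77)
  w20 <- with(curve$edges[curve$edges$s == 20, ], upper - lower)
  w200 <- with(curve$edges[curve$edges$s == 200, ], upper - lower)
  expect_gte(mean(w200 < w20), 0.95)

  # the S = 0 grid point carries the bare prior interval, wide by construction
  w0 <- with(curve$edges[curve$edges$s == 0, ], upper - lower)
  expect_true(all(w0 > w200))
  expect_equal(length(unique(w0)), 1)

  expect_true(is_stabilized(curve, "mean_degree", tol = 0.05))
})

test_that("b-SRI reliability curve has zero-width intervals at S = 1", {
  net <- generate_true_network(8, seed = 78)
  obs <- sample_observations(net, 41, seed = 79)
  curve <- subsample_stability(obs, grid_step = 1, method = "sri_bootstrap",
                               n_boot = 40, seed = 80)
  at1 <- curve$edges[curve$edges$s == 1, ]
  expect_true(all(at1$upper - at1$lower == 0))
})

test_that("subsampling modes and the degenerate grid warning behave", {
  net <- generate_true_network(6, seed = 81)
  obs <- sample_observations(net, 30, seed = 82)
  rand <- subsample_stability(obs, grid_step = 10, method = "clopper_pearson",
                              mode = "random", seed = 83)
  expect_equal(sort(unique(rand$edges$s)), c(10, 20, 30))
  expect_true(all(is.na(rand$mean_degree$lower)))
  expect_warning(
    single <- subsample_stability(obs, grid_step = 50,
                                  method = "clopper_pearson"),
    "single-point")
  expect_equal(unique(single$edges$s), 30)
})
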