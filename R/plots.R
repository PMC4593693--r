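#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot edge estimates with their 95% intervals
#'
#' Dyads ordered by point estimate, with the interval as a vertical range —
#' a quick view of how differentiated the relationships are and how much
#' uncertainty surrounds each.
#'
#' @param object An `edge_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot edge_estimates
#' @export
autoplot.edge_estimates <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      dyad = paste(.data$node_i, .data$node_j, sep = "-"))
  df$dyad <- stats::reorder(df$dyad, df$point)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dyad, y = .data$point)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower,
                                         ymax = .data$upper),
                            colour = "grey55") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "dyad (ordered by estimate)", y = "edge weight",
                  title = sprintf("%s estimates with %g%% intervals",
                                  attr(object, "method"),
                                  100 * attr(object, "level"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot node-metric uncertainty
#'
#' @param object A `metric_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metric_distribution
#' @export
autoplot.metric_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$node <- stats::reorder(df$node, df$point)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             size = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = attr(object, "metric"),
                  title = sprintf("weighted %s with %g%% intervals (%d replicates)",
                                  attr(object, "metric"),
                                  100 * attr(object, "level"),
                                  attr(object, "n_replicates"))) +
    ggplot2::theme_minimal()
}

#' Plot a subsampling reliability curve
#'
#' Mean weighted degree (with its 95% band where available) against
#' sampling effort; a flattening curve whose final increments overlap
#' suggests the network is adequately sampled.
#'
#' @param object A `reliability_curve`.
#' @param what `"mean_degree"` or `"edges"` (facet per dyad; intended for
#'   small networks).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot reliability_curve
#' @export
autoplot.reliability_curve <- function(object, what = c("mean_degree", "edges"),
                                       ...) {
  what <- match.arg(what)
  if (what == "mean_degree") {
    ggplot2::ggplot(object$mean_degree, ggplot2::aes(x = .data$s,
                                                     y = .data$point)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           fill = "grey80", na.rm = TRUE) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "sampling effort (units)", y = "mean weighted degree",
                    title = sprintf("reliability curve (%s)", object$method)) +
      ggplot2::theme_minimal()
  } else {
    df <- dplyr::mutate(object$edges,
                        dyad = paste(.data$node_i, .data$node_j, sep = "-"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$point)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           fill = "grey80") +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~dyad) +
      ggplot2::labs(x = "sampling effort (units)", y = "edge weight",
                    title = sprintf("edge-weight funnels (%s)", object$method)) +
      ggplot2::theme_minimal()
  }
}

#' Plot summarised simulation-study scores against sampling effort
#'
#' @param summary Output of [summarize_study()].
#' @param score One of `"mean_error"`, `"rank_correlation"`, `"fp_rate"`,
#'   `"fn_rate"`.
#' @return A ggplot with one line per method (median and 95% range across
#'   replicate networks).
#' @export
plot_study <- function(summary, score = "mean_error") {
  df <- dplyr::filter(summary, .data$score == !!score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$median,
                                   colour = .data$method,
                                   fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~eval_level) +
    ggplot2::labs(x = "number of sampling periods", y = score) +
    ggplot2::theme_minimal()
}
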