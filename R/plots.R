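# ggplot2 visualisations of sweeps, manifolds, policy curves and histograms.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a sweep metric over the (tau_m, v_th) grid
#'
#' @param object An `snn_sweep` (or `snn_efficiency`) tibble.
#' @param metric Column to plot (default `"accuracy"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snn_sweep <- function(object, metric = "accuracy", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(signif(.data$tau_m, 4)), y = factor(signif(.data$v_th, 4)),
    fill = .data[[metric]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::labs(
      x = expression(tau[m] ~ "(ms)"), y = expression(V[th] ~ "(V)"),
      title = sprintf("%s over the (tau_m, v_th) sweep", metric)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.snn_efficiency <- function(object, metric = "eas", ...) {
  autoplot.snn_sweep(object, metric = metric, ...)
}

#' Membership/boundary map of the operational manifold
#'
#' @param object A `manifold_result` from [manifold()].
#' @param ... Unused.
#' @return A ggplot object showing silent/saturated exteriors, the manifold
#'   interior and its boundary cells.
#' @export
autoplot.manifold_result <- function(object, ...) {
  df <- dplyr::mutate(object$sweep, cell = dplyr::case_when(
    .data$on_boundary ~ "boundary",
    .data$in_manifold ~ "interior",
    .data$mean_rate < object$spec$r_min ~ "silent",
    .data$mean_rate > object$spec$r_max ~ "saturated",
    TRUE ~ "low accuracy"
  ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(signif(.data$tau_m, 4)), y = factor(signif(.data$v_th, 4)),
    fill = .data$cell
  )) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(
      interior = "#1b9e77", boundary = "#66c2a5", silent = "#d9d9d9",
      saturated = "#d95f02", `low accuracy` = "#fdd49e"
    )) +
    ggplot2::labs(x = expression(tau[m] ~ "(ms)"),
                  y = expression(V[th] ~ "(V)"),
                  title = "Operational manifold") +
    ggplot2::theme_minimal()
}

#' Accuracy versus inference horizon by membrane policy
#'
#' @param object A `policy_curve` from [evaluate_policy_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.policy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$t_steps, y = .data$accuracy, colour = .data$policy
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "inference timesteps T", y = "test accuracy",
                  colour = "policy") +
    ggplot2::theme_minimal()
}

#' Class-conditional output spike histogram
#'
#' @param object An `output_histogram` from [class_output_histogram()].
#' @param ... Unused.
#' @return A ggplot object: one panel per timestep, mean spike count per
#'   output neuron.
#' @export
autoplot.output_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$neuron), y = .data$mean_count
  )) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::facet_wrap(~t, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "output neuron", y = "mean spike count") +
    ggplot2::theme_minimal()
}
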