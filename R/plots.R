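#' Plot the posterior prediction curve of a fit
#'
#' Draws the observed effects (point size inversely related to their
#' standard error) against relative assay temperature, with the
#' population-level posterior median curve and its 95% compatibility
#' band for the moderator setting supplied.
#'
#' @param object A `tpc_meta_fit`.
#' @param moderators Passed to [predict_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tpc_meta_fit <- function(object, moderators = list(), ...) {
  pred <- predict_curve(object, moderators = moderators)
  eff <- object$design$effects
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$rel_assay_temp)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), colour = "steelblue") +
    ggplot2::geom_point(
      data = eff,
      ggplot2::aes(
        x = .data$rel_assay_temp, y = .data$rel_fitness,
        size = 1 / .data$rel_fitness_se
      ),
      alpha = 0.4, show.legend = FALSE
    ) +
    ggplot2::scale_size(range = c(0.5, 3)) +
    ggplot2::labs(
      x = "Relative assay temperature (°C)",
      y = "Relative fitness",
      title = object$spec$label
    ) +
    ggplot2::theme_minimal()
}

#' Funnel plot of effects against their standard error
#'
#' @param object A `tpc_funnel` from [bias_test()].
#' @param ... Unused.
#' @return A ggplot object: effects on the x axis, standard error on a
#'   reversed y axis, with the usual pseudo-confidence funnel around the
#'   unweighted mean.
#' @exportS3Method ggplot2::autoplot
autoplot.tpc_funnel <- function(object, ...) {
  f <- object$funnel
  centre <- mean(f$effect)
  se_grid <- seq(0, max(f$se) * 1.05, length.out = 50)
  band <- tibble::tibble(
    se = se_grid,
    lo = centre - 1.96 * se_grid,
    hi = centre + 1.96 * se_grid
  )
  ggplot2::ggplot(f, ggplot2::aes(x = .data$effect, y = .data$se)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = NULL, xmin = .data$lo, xmax = .data$hi, y = .data$se),
      fill = "grey85", orientation = "y"
    ) +
    ggplot2::geom_vline(xintercept = centre, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "Relative fitness", y = "Standard error",
      subtitle = paste("Verdict:", object$verdict)
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated thermal performance curves of a scenario
#'
#' Visualises the ancestor curve and its scenario-transformed derived
#' curve for a baseline shape, marking the selection temperature.
#'
#' @param scn A [sim_scenario()].
#' @param shape Baseline ancestor [tpc_shape()].
#' @return A ggplot object.
#' @export
plot_scenario <- function(scn, shape = tpc_shape()) {
  derived <- .derive_shape(shape, scn)
  grid <- seq(shape$t_opt - 15, max(shape$t_max, derived$t_max) + 2,
    length.out = 300
  )
  df <- dplyr::bind_rows(
    tibble::tibble(temp = grid, fitness = tpc_value(shape, grid), line = "ancestor"),
    tibble::tibble(temp = grid, fitness = tpc_value(derived, grid), line = "derived")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$temp, .data$fitness, colour = .data$line)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = shape$t_opt + scn$selection_shift,
      linetype = "dotted"
    ) +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Fitness",
      title = scn$scenario, colour = NULL
    ) +
    ggplot2::theme_minimal()
}
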