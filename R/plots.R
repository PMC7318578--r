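#' Plot a modified Arrhenius fit
#'
#' Points (with delta-method error bars when SEs are available) and the
#' fitted line, on the ln(Vmax ratio) vs 1000/T axes.
#'
#' @param object An `arrhenius_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  s <- object$series
  pair <- object$pair %||% c("pathway 1", "pathway 2")
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$inv_kK, y = .data$log_vmax_ratio)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(1000 / italic(T) ~ (K^-1)),
      y = sprintf("ln(Vmax %s / Vmax %s)", pair[1], pair[2]),
      subtitle = sprintf("slope %.2f K, intercept %.1f, R² %.2f, Δ %.1f kJ/mol",
                         object$slope, object$intercept, object$r_squared,
                         object$delta))
  if ("log_vmax_ratio_se" %in% names(s) && all(is.finite(s$log_vmax_ratio_se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$log_vmax_ratio - .data$log_vmax_ratio_se,
                   ymax = .data$log_vmax_ratio + .data$log_vmax_ratio_se),
      width = 0)
  }
  p
}

#' Plot a Michaelis-Menten fit
#'
#' Observed velocities and the fitted saturation curve.
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(
    substrate_uM = seq(0, max(object$data$substrate_uM), length.out = 200))
  grid$velocity <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$substrate_uM, y = .data$velocity)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[S] (µM)",
                  y = "v (nmol min⁻¹ nmol⁻¹)",
                  subtitle = sprintf("Vmax %.3g ± %.2g, KM %.3g ± %.2g µM",
                                     object$Vmax, object$Vmax_SE,
                                     object$KM, object$KM_SE))
}

#' Bar chart of active-pose fractions
#'
#' One bar per (trajectory, SOM) from an [active_fraction()] report.
#'
#' @param report Tibble from [active_fraction()].
#' @return A ggplot object.
#' @export
plot_pose_fractions <- function(report) {
  require_columns(report, c("trajectory", "som", "percent_active"),
                  "Pose fraction report")
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$som, y = .data$percent_active,
                               fill = .data$trajectory)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Site of metabolism", y = "% catalytically active frames",
                  fill = "Trajectory") +
    ggplot2::ylim(0, 100)
}
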