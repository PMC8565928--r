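#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_col
#'   geom_abline geom_hline facet_grid facet_wrap labs theme_minimal
#'   scale_fill_viridis_c autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a characteristic-speed profile
#'
#' @param profile tibble from [characteristic_speed()] or
#'   [make_characteristic_profile()].
#' @return a ggplot.
#' @export
plot_characteristic_profile <- function(profile) {
  ggplot(profile, aes(x = .data$bin_center, y = .data$vbar,
                      colour = .data$direction)) +
    geom_line() +
    labs(x = "position (cm)", y = "characteristic speed (cm/s)",
         colour = "direction") +
    theme_minimal()
}

#' Plot a firing rate map with detected fields
#'
#' @param rate_map tibble from [compute_rate_map()].
#' @param fields optional field table ([detect_fields()]) to overlay.
#' @return a ggplot.
#' @export
plot_rate_map <- function(rate_map, fields = NULL) {
  p <- ggplot(rate_map, aes(x = .data$bin_center, y = .data$rate)) +
    geom_line() +
    labs(x = "position (cm)", y = "firing rate (Hz)") +
    theme_minimal()
  if (!is.null(fields) && nrow(fields) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = c(fields$start, fields$end),
                                 linetype = "dashed", colour = "grey50") +
      geom_point(data = tibble::tibble(x = fields$peak_x,
                                       y = fields$peak_rate),
                 aes(x = .data$x, y = .data$y), colour = "orange", size = 2)
  }
  p
}

#' Plot a phase precession cloud with its wrapped-ODR fit
#'
#' The fitted line is drawn along with its +-1 phase-wrapped copies.
#'
#' @param cloud tibble from [build_cloud()].
#' @param fit optional `precession_fit`.
#' @return a ggplot.
#' @export
plot_phase_precession <- function(cloud, fit = NULL) {
  p <- ggplot(cloud, aes(x = .data$position_norm, y = .data$phase_norm,
                         colour = .data$speed)) +
    geom_point(alpha = 0.7) +
    scale_fill_viridis_c() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "position in field (normalized)",
         y = "theta phase (normalized)", colour = "speed (cm/s)") +
    theme_minimal()
  if (!is.null(fit)) {
    p <- p + geom_abline(slope = fit$slope_norm,
                         intercept = fit$intercept + c(-1, 0, 1),
                         colour = "orange")
  }
  p
}

#' Plot a decoded theta-cycle posterior
#'
#' @param object a `posterior_matrix`.
#' @param ... unused.
#' @return a ggplot: decoded probability by phase bin and relative
#'   position.
#' @export
autoplot.posterior_matrix <- function(object, ...) {
  d <- tidyr::expand_grid(col = seq_along(object$window_start_deg),
                          row = seq_along(object$rel_pos)) |>
    dplyr::mutate(
      phase = object$window_start_deg[.data$col] + 45,
      pos = object$rel_pos[.data$row],
      p = as.numeric(object$P)[(.data$col - 1) * length(object$rel_pos) +
                                 .data$row])
  ggplot(d, aes(x = .data$phase, y = .data$pos, fill = .data$p)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "white") +
    labs(x = "theta phase (deg, window center)",
         y = "position relative to animal (cm)", fill = "P(x|n)") +
    theme_minimal()
}

#' Plot the sign matrix of a model comparison
#'
#' @param object a `comparison_summary`.
#' @param ... unused.
#' @return a ggplot tile panel of increase/flat/decrease calls.
#' @export
autoplot.comparison_summary <- function(object, ...) {
  ggplot(object$signs,
         aes(x = .data$scheme, y = .data$metric, fill = .data$call)) +
    geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(increase = "#2c7fb8",
                                          flat = "grey80",
                                          decrease = "#d95f0e")) +
    labs(x = NULL, y = NULL, fill = "speed effect") +
    theme_minimal()
}

#' Plot the look-ahead time fit
#'
#' @param object a `tau_theta_fit`.
#' @param ... unused.
#' @return a ggplot of inverse slope vs characteristic speed with the
#'   through-origin fit.
#' @export
autoplot.tau_theta_fit <- function(object, ...) {
  ggplot(object$points, aes(x = .data$vbar, y = .data$inv_slope)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = object$tau_theta, intercept = 0,
                colour = "orange") +
    labs(x = "characteristic speed (cm/s)",
         y = "inverse precession slope 360/|m| (cm)") +
    theme_minimal()
}
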