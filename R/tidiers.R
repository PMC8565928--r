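#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a wrapped-ODR precession fit
#'
#' @param x a `precession_fit`.
#' @param extent optional field extent (cm) to also report the slope in
#'   deg/cm.
#' @param ... unused.
#' @return one-row tibble with `slope_norm`, `intercept`, `error`, `n`
#'   (and `slope_deg_per_cm` when `extent` is given).
#' @export
tidy.precession_fit <- function(x, extent = NULL, ...) {
  out <- tibble::tibble(slope_norm = x$slope_norm, intercept = x$intercept,
                        error = x$error, n = x$n)
  if (!is.null(extent)) {
    out$slope_deg_per_cm <- slope_to_physical(x, extent)
  }
  out
}

#' @rdname tidy.precession_fit
#' @export
glance.precession_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, error = x$error, n = x$n)
}

#' Tidy a look-ahead time fit
#'
#' @param x a `tau_theta_fit`.
#' @param ... unused.
#' @return the per-field points with the fitted values.
#' @export
tidy.tau_theta_fit <- function(x, ...) {
  dplyr::mutate(x$points, fitted = x$tau_theta * .data$vbar)
}

#' @rdname tidy.tau_theta_fit
#' @export
glance.tau_theta_fit <- function(x, ...) {
  tibble::tibble(tau_theta = x$tau_theta, r2 = x$r2, n = x$n)
}

#' Tidy a within-field speed-effect test
#'
#' @param x a `within_field_test`.
#' @param ... unused.
#' @return the per-field regression slopes.
#' @export
tidy.within_field_test <- function(x, ...) x$slopes

#' @rdname tidy.within_field_test
#' @export
glance.within_field_test <- function(x, ...) {
  tibble::tibble(p = x$p, statistic = x$statistic,
                 median_slope = x$median_slope, n_fields = x$n_fields)
}

#' Tidy a variance partition
#'
#' @param x a `variance_partition`.
#' @param ... unused.
#' @return tibble with one row per predictor: `term`, `unique_r2`,
#'   `lrt_p`.
#' @export
tidy.variance_partition <- function(x, ...) {
  tibble::tibble(term = names(x$unique_r2),
                 unique_r2 = unname(x$unique_r2),
                 lrt_p = unname(x$lrt_p))
}

#' @rdname tidy.variance_partition
#' @export
glance.variance_partition <- function(x, ...) {
  tibble::tibble(r2_full = x$r2_full, n = x$n)
}

#' Tidy a three-scheme comparison summary
#'
#' @param x a `comparison_summary`.
#' @param ... unused.
#' @return the sign table (scheme, metric, call, tau, p).
#' @export
tidy.comparison_summary <- function(x, ...) x$signs

#' @rdname tidy.comparison_summary
#' @export
glance.comparison_summary <- function(x, ...) {
  x$signs |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(
      pooled_increases = sum(.data$call == "increase" &
                               startsWith(.data$metric, "pooled")),
      within_flat = sum(.data$call == "flat" &
                          startsWith(.data$metric, "within")),
      .groups = "drop")
}

#' @export
print.precession_fit <- function(x, ...) {
  cat("Wrapped-ODR precession fit:", x$n, "spikes\n")
  cat(sprintf("  slope (normalized) %.4f, intercept %.4f, mean orthogonal error %.4f\n",
              x$slope_norm, x$intercept, x$error))
  invisible(x)
}

#' @export
print.tau_theta_fit <- function(x, ...) {
  cat(sprintf("Look-ahead time fit: tau_theta = %.3f s (%d fields, R^2 = %.2f)\n",
              x$tau_theta, x$n, x$r2))
  invisible(x)
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Three-scheme sweep model comparison\n")
  wide <- tidyr::pivot_wider(x$signs[, c("scheme", "metric", "call")],
                             names_from = "metric", values_from = "call")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' @export
print.theta_session <- function(x, ...) {
  cat(sprintf("Simulated linear-track session: %s sweep, %d cells, %.0f cm track, %.0f s\n",
              x$truth$params$scheme, length(x$truth$centers),
              x$track$length, max(x$tracking$t)))
  cat(sprintf("  %d spikes, %d theta cycles\n", nrow(x$spikes),
              nrow(x$theta$cycles)))
  invisible(x)
}

#' @export
print.theta_analysis <- function(x, ...) {
  cat(sprintf("Session analysis: %d fields, phase offset %g deg\n",
              nrow(x$fields), x$phase_offset))
  if (!is.null(x$trajectories)) {
    cat(sprintf("  %d decoded cycles (%d well covered)\n",
                nrow(x$trajectories), sum(x$trajectories$ok)))
  }
  invisible(x)
}
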