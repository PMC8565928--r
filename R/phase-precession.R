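#' Build a phase precession cloud for one field
#'
#' Collects the spikes of the field's cell that fall inside the field
#' extent, during runs in the field's direction and within significant
#' theta cycles. Positions are normalized by the field extent and phases
#' by 360 degrees, so both axes contribute equally to orthogonal errors.
#' Position is measured along the direction of travel (0 at the field
#' entry), so phase precession has a negative slope for both running
#' directions.
#'
#' @param spikes annotated spike tibble with columns `cell`, `t`, `x`,
#'   `phase`, `v`, `direction`, `run_id`, `significant`.
#' @param cell cell id.
#' @param direction running direction of the field.
#' @param start,end field extent (cm).
#' @param phase_offset session-wide phase offset (deg) added before
#'   normalization.
#' @return tibble with `t`, `position_norm`, `phase_norm`, `speed`,
#'   `run_id`.
#' @export
build_cloud <- function(spikes, cell, direction, start, end,
                        phase_offset = 0) {
  s <- spikes[spikes$cell == cell & spikes$direction == direction &
                spikes$significant & spikes$x >= start & spikes$x <= end, ]
  pos <- if (direction == "left") (end - s$x) / (end - start)
         else (s$x - start) / (end - start)
  tibble::tibble(
    t = s$t,
    position_norm = pos,
    phase_norm = ((s$phase + phase_offset) %% 360) / 360,
    speed = s$v,
    run_id = s$run_id
  )
}

tls_line <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  cv <- cbind(x - xm, y - ym)
  if (nrow(cv) < 2 || (var(x) == 0 && var(y) == 0)) return(c(0, ym))
  e <- eigen(crossprod(cv) / nrow(cv), symmetric = TRUE)
  v <- e$vectors[, 1]
  if (abs(v[1]) < 1e-12) {
    slope <- sign(v[2]) * 1e6
  } else {
    slope <- v[2] / v[1]
  }
  c(slope, ym - slope * xm)
}

odr_wrapped_dist2 <- function(par, x, y, wrap_lo = 0.3, wrap_hi = 0.7) {
  a <- par[1]; b <- par[2]
  denom <- 1 + a^2
  d0 <- (a * x + b - y)^2 / denom
  up <- y < wrap_lo   # candidate shift +1
  dn <- y > wrap_hi   # candidate shift -1
  dalt <- rep(Inf, length(y))
  dalt[up] <- (a * x[up] + b - (y[up] + 1))^2 / denom
  dalt[dn] <- (a * x[dn] + b - (y[dn] - 1))^2 / denom
  pmin(d0, dalt)
}

#' Wrapped orthogonal-distance regression of a precession cloud
#'
#' Fits the line minimizing the sum of squared orthogonal distances in
#' the normalized (position, phase) plane. Points with normalized phase
#' below 0.3 (above 0.7) may alternatively be matched after a +1 (-1)
#' phase shift, whichever orthogonal distance is smaller; this resolves
#' the ambiguity of spikes near the cycle boundary. The objective is
#' minimized with Nelder-Mead, multi-started from the total-least-squares
#' solutions of the three wrap configurations (no shift, +1 below 0.3,
#' -1 above 0.7).
#'
#' @param cloud tibble with `position_norm`, `phase_norm`.
#' @param wrap_lo,wrap_hi wrap-eligibility thresholds on normalized
#'   phase.
#' @return object of class `precession_fit`: list with `slope_norm`,
#'   `intercept`, `error` (mean orthogonal distance), `n`, `objective`.
#' @export
fit_odr_wrapped <- function(cloud, wrap_lo = 0.3, wrap_hi = 0.7) {
  x <- cloud$position_norm
  y <- cloud$phase_norm
  abort_if(length(x) < 2, "need at least 2 points")
  abort_if(all(x == x[1]) && all(y == y[1]), "all points identical")
  obj <- function(par) sum(odr_wrapped_dist2(par, x, y, wrap_lo, wrap_hi))
  y_up <- y + (y < wrap_lo)
  y_dn <- y - (y > wrap_hi)
  y_both <- y + (y < wrap_lo) - (y > wrap_hi)
  starts <- list(tls_line(x, y), tls_line(x, y_up), tls_line(x, y_dn),
                 tls_line(x, y_both))
  best <- NULL
  for (s in starts) {
    s[1] <- max(min(s[1], 1e3), -1e3)
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(slope_norm = best$par[1], intercept = best$par[2],
                 error = mean(sqrt(odr_wrapped_dist2(best$par, x, y,
                                                     wrap_lo, wrap_hi))),
                 n = length(x), objective = best$value),
            class = "precession_fit")
}

#' Convert a normalized precession slope to physical units
#'
#' @param fit a `precession_fit` (or its normalized slope).
#' @param extent field extent (cm).
#' @return slope in degrees per cm.
#' @export
slope_to_physical <- function(fit, extent) {
  abort_if(extent <= 0, "extent must be positive")
  slope <- if (inherits(fit, "precession_fit")) fit$slope_norm else fit
  slope * 360 / extent
}

#' Pooled phase precession slopes per speed bin
#'
#' Fits the wrapped orthogonal regression on the sub-cloud of spikes
#' emitted at speeds inside each overlapping speed bin. A bin is only
#' analyzed when the field was sufficiently sampled at that speed (the
#' same sampling-index gate as the per-speed field sizes) and the
#' sub-cloud has at least `min_spikes` spikes. Positions stay
#' normalized by the all-speed field extent.
#'
#' @param cloud output of [build_cloud()].
#' @param extent field extent (cm).
#' @param min_spikes minimum spikes per bin, default 12.
#' @param bins_ok speed bins passing the sampling-index gate (default:
#'   all bins).
#' @return tibble with `bin`, `center`, `slope_norm`,
#'   `slope_deg_per_cm`, `error`, `n_spikes`.
#' @export
pooled_slopes_by_speed <- function(cloud, extent, min_spikes = 12,
                                   bins_ok = NULL) {
  sb <- speed_bins()
  if (!is.null(bins_ok)) sb <- sb[sb$bin %in% bins_ok, ]
  purrr::map_dfr(seq_len(nrow(sb)), function(i) {
    sub <- cloud[cloud$speed >= sb$lo[i] & cloud$speed < sb$hi[i], ]
    if (nrow(sub) < min_spikes) return(NULL)
    f <- fit_odr_wrapped(sub)
    tibble::tibble(bin = sb$bin[i], center = sb$center[i],
                   slope_norm = f$slope_norm,
                   slope_deg_per_cm = slope_to_physical(f, extent),
                   error = f$error, n_spikes = f$n)
  })
}

#' Phase precession slopes in single passes through a field
#'
#' One fit per traversal of the field. A pass is analyzed only if its
#' mean speed exceeds 2 cm/s, it contains at least 6 spikes, the
#' interval between first and last spike exceeds 400 ms, the coefficient
#' of variation of instantaneous speed during the pass is below 0.3, and
#' the pass samples the field sufficiently (sampling index >= 0.4).
#'
#' @param cloud output of [build_cloud()] (carries `run_id`).
#' @param tracking annotated tracking tibble (`t`, `x`, `v`, `run_id`).
#' @param start,end field extent (cm).
#' @param spatial_bin bin width for the pass sampling index (cm).
#' @param min_speed,min_spikes,min_duration,max_cv,min_sampling
#'   inclusion thresholds.
#' @return tibble with `run_id`, `slope_norm`, `slope_deg_per_cm`,
#'   `error`, `n_spikes`, `mean_speed`, `cv_speed`.
#' @export
single_pass_slopes <- function(cloud, tracking, start, end,
                               spatial_bin = 4, min_speed = 2,
                               min_spikes = 6, min_duration = 0.4,
                               max_cv = 0.3, min_sampling = 0.4) {
  extent <- end - start
  runs <- unique(cloud$run_id)
  runs <- runs[!is.na(runs)]
  edges <- seq(start, end, by = spatial_bin)
  if (edges[length(edges)] < end) edges <- c(edges, end)
  purrr::map_dfr(runs, function(r) {
    sub <- cloud[!is.na(cloud$run_id) & cloud$run_id == r, ]
    if (nrow(sub) < min_spikes) return(NULL)
    if (diff(range(sub$t)) <= min_duration) return(NULL)
    tr <- tracking[!is.na(tracking$run_id) & tracking$run_id == r &
                     tracking$x >= start & tracking$x <= end, ]
    if (nrow(tr) < 2) return(NULL)
    vpass <- abs(tr$v)
    if (mean(vpass) <= min_speed) return(NULL)
    if (sd(vpass) / mean(vpass) >= max_cv) return(NULL)
    occ <- tabulate(findInterval(tr$x, edges, rightmost.closed = TRUE),
                    nbins = length(edges) - 1)
    if (sampling_index(occ > 0) < min_sampling) return(NULL)
    f <- fit_odr_wrapped(sub)
    tibble::tibble(run_id = r, slope_norm = f$slope_norm,
                   slope_deg_per_cm = slope_to_physical(f, extent),
                   error = f$error, n_spikes = f$n,
                   mean_speed = mean(vpass),
                   cv_speed = sd(vpass) / mean(vpass))
  })
}
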