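#' Overlapping speed bins
#'
#' Seven 20 cm/s wide speed bins starting at 2 cm/s in increments of
#' 10 cm/s: \[2,22), \[12,32), ..., \[62,82). Because consecutive bins
#' overlap by 10 cm/s, a speed can fall into zero, one or two bins.
#'
#' @return tibble with columns `bin`, `lo`, `hi`, `center` (cm/s).
#' @export
speed_bins <- function() {
  lo <- seq(2, 62, by = 10)
  tibble::tibble(bin = seq_along(lo), lo = lo, hi = lo + 20, center = lo + 10)
}

#' Assign speeds to overlapping speed bins
#'
#' @param v numeric vector of speeds (cm/s).
#' @return tibble with columns `index` (position in `v`), `v`, `bin`,
#'   `center`; one row per (speed, containing bin) pair.
#' @examples
#' assign_speed_bins(c(15, 1, 70))
#' @export
assign_speed_bins <- function(v) {
  sb <- speed_bins()
  purrr::map_dfr(seq_len(nrow(sb)), function(i) {
    hit <- which(v >= sb$lo[i] & v < sb$hi[i])
    tibble::tibble(index = hit, v = v[hit], bin = sb$bin[i], center = sb$center[i])
  }) |>
    dplyr::arrange(.data$index, .data$bin)
}

#' Instantaneous running speed from positions
#'
#' Central difference of position, smoothed with a Gaussian filter with a
#' standard deviation of 100 ms. Endpoints use one-sided differences.
#'
#' @param x positions (cm), uniformly sampled.
#' @param fs sampling rate (Hz).
#' @param sigma_s smoothing standard deviation (s), default 0.1.
#' @return speed series (cm/s), same length as `x`. Note the sign is kept:
#'   use `abs()` for speed regardless of direction.
#' @export
compute_speed <- function(x, fs, sigma_s = 0.1) {
  abort_if(length(x) < 3, "need at least 3 position samples")
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  gauss_smooth(v, sigma_s * fs)
}

#' Acceleration from smoothed speed
#'
#' First difference of the smoothed speed series, scaled by the sampling
#' rate; the last sample repeats the previous value to preserve length.
#'
#' @param v smoothed speed series (cm/s).
#' @param fs sampling rate (Hz).
#' @return acceleration series (cm/s^2).
#' @export
compute_acceleration <- function(v, fs) {
  n <- length(v)
  if (n < 2) return(rep(0, n))
  a <- c(diff(v) * fs, NA_real_)
  a[n] <- a[n - 1]
  a
}

#' Segment corner-to-corner runs
#'
#' Identifies maximal epochs in which the animal moves monotonically from
#' one end zone of the track to the other. Everything else is labeled as a
#' pause. An end zone is the region within `end_zone` cm of a track end.
#'
#' @param tracking tibble with columns `t`, `x`.
#' @param track_length track length (cm).
#' @param end_zone width of the corner zones (cm), default 5.
#' @param min_step minimum per-sample displacement (cm) counted as movement.
#' @return `tracking` with added columns `direction` ("right", "left",
#'   "pause") and `run_id` (NA during pauses).
#' @export
segment_runs <- function(tracking, track_length, end_zone = 5, min_step = 0.05) {
  x <- tracking$x
  n <- length(x)
  s <- sign(diff(x))
  s[abs(diff(x)) < min_step] <- 0
  s <- c(s, 0)
  direction <- rep("pause", n)
  run_id <- rep(NA_integer_, n)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  rid <- 0L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0) next
    i0 <- starts[k]
    i1 <- min(ends[k] + 1L, n)  # segment covers displacement i0..i1
    x0 <- x[i0]; x1 <- x[i1]
    from_left <- x0 <= end_zone && x1 >= track_length - end_zone
    from_right <- x0 >= track_length - end_zone && x1 <= end_zone
    if (from_left || from_right) {
      rid <- rid + 1L
      direction[i0:i1] <- if (r$values[k] > 0) "right" else "left"
      run_id[i0:i1] <- rid
    }
  }
  tracking$direction <- direction
  tracking$run_id <- run_id
  tracking
}

#' Characteristic running speed profile
#'
#' Mean speed in 4 cm spatial bins for one running direction, after
#' discarding samples slower than 10 cm/s that occur farther than 40 cm
#' from either track end (mid-track stops are atypical; slow running near
#' the corners is the norm and is retained). A mean acceleration per bin
#' is computed from the same included samples.
#'
#' @param tracking tibble with `x`, `v`, `a`, `direction`, `run_id`
#'   (see [segment_runs()] and [compute_speed()]).
#' @param track_length track length (cm).
#' @param direction "right" or "left".
#' @param bin spatial bin width (cm), default 4.
#' @param min_speed mid-track discard threshold (cm/s), default 10.
#' @param end_margin corner exemption margin (cm), default 40.
#' @param fill interpolate across empty bins? Interpolated bins are
#'   flagged in the `interpolated` column.
#' @return tibble with `direction`, `bin_left`, `bin_center`, `vbar`,
#'   `abar`, `n`, `interpolated`.
#' @export
characteristic_speed <- function(tracking, track_length, direction,
                                 bin = 4, min_speed = 10, end_margin = 40,
                                 fill = TRUE) {
  keep <- !is.na(tracking$run_id) & tracking$direction == direction
  abort_if(!any(keep), paste0("no runs in direction '", direction, "'"))
  x <- tracking$x[keep]
  v <- abs(tracking$v[keep])
  # acceleration in the travel frame: for leftward runs d|v|/dt = -dv/dt
  a <- if (direction == "left") -tracking$a[keep] else tracking$a[keep]
  near_end <- x <= end_margin | x >= track_length - end_margin
  inc <- v >= min_speed | near_end
  edges <- seq(0, track_length, by = bin)
  nb <- length(edges) - 1L
  idx <- pmin(pmax(findInterval(x[inc], edges, rightmost.closed = TRUE), 1L), nb)
  vbar <- tapply(v[inc], factor(idx, levels = seq_len(nb)), mean)
  abar <- tapply(a[inc], factor(idx, levels = seq_len(nb)), mean)
  nobs <- tapply(rep(1, sum(inc)), factor(idx, levels = seq_len(nb)), sum)
  out <- tibble::tibble(
    direction = direction,
    bin_left = edges[-length(edges)],
    bin_center = edges[-length(edges)] + bin / 2,
    vbar = as.numeric(vbar),
    abar = as.numeric(abar),
    n = as.integer(ifelse(is.na(nobs), 0L, nobs)),
    interpolated = FALSE
  )
  abort_if(all(is.na(out$vbar)), "all samples excluded in every bin")
  if (fill && anyNA(out$vbar)) {
    miss <- is.na(out$vbar)
    out$vbar[miss] <- interp1(out$bin_center[!miss], out$vbar[!miss],
                              out$bin_center[miss])
    am <- is.na(out$abar)
    out$abar[am] <- interp1(out$bin_center[!am], out$abar[!am], out$bin_center[am])
    out$interpolated <- miss
  }
  out
}

#' Look up the characteristic speed at arbitrary positions
#'
#' @param profile output of [characteristic_speed()] or
#'   [make_characteristic_profile()] (possibly with both directions).
#' @param x positions (cm).
#' @param direction single direction, or vector matched to `x`.
#' @return characteristic speed at `x` (cm/s), linearly interpolated
#'   between bin centers and clamped at the track ends.
#' @export
profile_speed_at <- function(profile, x, direction) {
  if (length(direction) == 1L) {
    p <- profile[profile$direction == direction, ]
    abort_if(nrow(p) == 0, paste0("profile has no direction '", direction, "'"))
    return(interp1(p$bin_center, p$vbar, x))
  }
  out <- numeric(length(x))
  for (d in unique(direction)) {
    i <- direction == d
    p <- profile[profile$direction == d, ]
    abort_if(nrow(p) == 0, paste0("profile has no direction '", d, "'"))
    out[i] <- interp1(p$bin_center, p$vbar, x[i])
  }
  out
}

#' Annotate a tracking table with speed, acceleration and run epochs
#'
#' @param tracking tibble with `t`, `x` uniformly sampled.
#' @param track_length track length (cm).
#' @param fs tracking sampling rate (Hz); inferred from `t` if missing.
#' @return tracking tibble with `v` (signed), `a`, `direction`, `run_id`.
#' @export
annotate_behavior <- function(tracking, track_length, fs = NULL) {
  fs <- fs %||% (1 / stats::median(diff(tracking$t)))
  tracking$v <- compute_speed(tracking$x, fs)
  tracking$a <- compute_acceleration(tracking$v, fs)
  segment_runs(tracking, track_length)
}
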