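#' Spatially binned firing rate map
#'
#' Firing rate (spike count over occupancy) in 4 cm bins, smoothed with
#' a 6 cm Gaussian, restricted to in-run, theta-significant samples of
#' one running direction. Unvisited bins enter the smoothing with a
#' rate of zero, so the smoothing bridges occupancy gaps of one or two
#' bins but pulls the rate below threshold across wider gaps (which is
#' what makes the three-zero-occupancy-bins incompleteness rule bite).
#' When a speed bin is given, counts and occupancy are restricted to
#' samples whose speed lies in the bin.
#'
#' @param spike_x spike positions (cm) already filtered to the cell,
#'   direction and significant cycles.
#' @param occ_x positions (cm) of the included tracking samples.
#' @param fs tracking sampling rate (Hz).
#' @param track_length track length (cm).
#' @param bin spatial bin width (cm), default 4.
#' @param smooth_sigma smoothing standard deviation (cm), default 6.
#' @return tibble with `bin_left`, `bin_center`, `occupancy` (s),
#'   `count`, `rate_raw` (Hz), `rate` (smoothed, Hz).
#' @export
compute_rate_map <- function(spike_x, occ_x, fs, track_length, bin = 4,
                             smooth_sigma = 6) {
  abort_if(length(occ_x) == 0, "zero total occupancy")
  edges <- seq(0, track_length, by = bin)
  nb <- length(edges) - 1L
  occ <- tabulate(pmin(pmax(findInterval(occ_x, edges,
                                         rightmost.closed = TRUE), 1L), nb),
                  nbins = nb) / fs
  cnt <- tabulate(pmin(pmax(findInterval(spike_x, edges,
                                         rightmost.closed = TRUE), 1L), nb),
                  nbins = nb)
  rate_raw <- ifelse(occ > 0, cnt / occ, 0)
  rate <- gauss_smooth(rate_raw, smooth_sigma / bin)
  tibble::tibble(bin_left = edges[-length(edges)],
                 bin_center = edges[-length(edges)] + bin / 2,
                 occupancy = occ, rate_raw = rate_raw,
                 count = cnt, rate = rate)
}

# interpolated position where rate crosses `level` between bins j and j+1
cross_at <- function(centers, rate, j, level, going_out_left) {
  if (going_out_left) {
    # crossing between j (below) and j + 1 (above)
    centers[j] + (level - rate[j]) / (rate[j + 1] - rate[j]) *
      (centers[j + 1] - centers[j])
  } else {
    centers[j] + (rate[j] - level) / (rate[j] - rate[j + 1]) *
      (centers[j + 1] - centers[j])
  }
}

#' Detect place fields on a rate map
#'
#' Candidate fields form around local rate peaks above `min_peak` Hz.
#' The extent runs to where the rate falls below 15% of the peak,
#' interpolated between bin centers. A side cut by the track end is
#' undetected; the field is only accepted if the rate dropped below 66%
#' of the peak before the edge on that side. A side whose threshold
#' crossing is separated from the peak by more than three consecutive
#' zero-occupancy bins is likewise treated as undetected (incomplete).
#' Fields need at least `min_spikes` spikes within the extent. As an
#' automated proxy for manual screening of overlapping precession
#' clouds, a field is rejected if its extent contains a secondary local
#' maximum of at least 50% of the peak separated from it by a trough of
#' at most 50% of the peak.
#'
#' @param rate_map output of [compute_rate_map()].
#' @param spike_x spike positions used for the map (cm).
#' @param min_peak minimum peak rate (Hz), default 2.
#' @param min_spikes minimum spikes within the extent, default 25.
#' @param thresh_frac extent threshold as a fraction of peak, 0.15.
#' @param edge_frac acceptance threshold for edge-cut sides, 0.66.
#' @param max_zero_occ maximum run of zero-occupancy bins between peak
#'   and crossing, default 3.
#' @param screen apply the overlapping-cloud rejection proxy?
#' @return tibble with one row per field: `peak_x`, `peak_rate`,
#'   `start`, `end`, `start_detected`, `end_detected`, `incomplete`,
#'   `size`, `n_spikes`.
#' @export
detect_fields <- function(rate_map, spike_x, min_peak = 2, min_spikes = 25,
                          thresh_frac = 0.15, edge_frac = 0.66,
                          max_zero_occ = 3, screen = TRUE) {
  r <- rate_map$rate
  centers <- rate_map$bin_center
  occ <- rate_map$occupancy
  nb <- length(r)
  empty <- tibble::tibble(peak_x = numeric(), peak_rate = numeric(),
                          start = numeric(), end = numeric(),
                          start_detected = logical(),
                          end_detected = logical(),
                          incomplete = logical(), size = numeric(),
                          n_spikes = integer())
  if (nb < 3) return(empty)
  is_peak <- which(r >= c(-Inf, r[-nb]) & r > c(r[-1], -Inf) & r >= min_peak)
  if (length(is_peak) == 0) return(empty)
  is_peak <- is_peak[order(r[is_peak], decreasing = TRUE)]
  claimed <- rep(FALSE, nb)
  out <- list()
  for (p in is_peak) {
    if (claimed[p]) next
    peak <- r[p]
    thr <- thresh_frac * peak
    # expand left
    jl <- p
    while (jl > 1 && r[jl - 1] >= thr) jl <- jl - 1
    start_detected <- jl > 1
    start <- if (start_detected) cross_at(centers, r, jl - 1, thr, TRUE)
             else centers[1] - 2
    # expand right
    jr <- p
    while (jr < nb && r[jr + 1] >= thr) jr <- jr + 1
    end_detected <- jr < nb
    end <- if (end_detected) cross_at(centers, r, jr, thr, FALSE)
           else centers[nb] + 2
    # edge-cut sides: accept only if the rate dipped below 66% of peak
    ok <- TRUE
    if (!start_detected && min(r[jl:p]) > edge_frac * peak) ok <- FALSE
    if (!end_detected && min(r[p:jr]) > edge_frac * peak) ok <- FALSE
    # occupancy gaps between peak and crossing undermine that side
    if (start_detected && max_zero_run(occ[jl:p]) > max_zero_occ)
      start_detected <- FALSE
    if (end_detected && max_zero_run(occ[p:jr]) > max_zero_occ)
      end_detected <- FALSE
    claimed[jl:jr] <- TRUE
    if (!ok) next
    if (!start_detected && !end_detected) next
    if (screen && has_overlapping_bump(r[jl:jr], p - jl + 1L)) next
    ns <- sum(spike_x >= start & spike_x <= end)
    if (ns < min_spikes) next
    size <- if (start_detected && end_detected) end - start
            else if (end_detected) 2 * (end - centers[p])
            else 2 * (centers[p] - start)
    out[[length(out) + 1L]] <- tibble::tibble(
      peak_x = centers[p], peak_rate = peak, start = start, end = end,
      start_detected = start_detected, end_detected = end_detected,
      incomplete = !(start_detected && end_detected), size = size,
      n_spikes = as.integer(ns))
  }
  if (length(out) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$peak_x)
}

max_zero_run <- function(x) {
  if (!any(x == 0)) return(0L)
  r <- rle(x == 0)
  max(r$lengths[r$values])
}

has_overlapping_bump <- function(r, p) {
  n <- length(r)
  if (n < 3) return(FALSE)
  peak <- r[p]
  locmax <- which(r >= c(-Inf, r[-n]) & r > c(r[-1], -Inf))
  locmax <- setdiff(locmax, p)
  for (q in locmax) {
    if (r[q] < 0.5 * peak) next
    rng <- if (q < p) q:p else p:q
    if (min(r[rng]) <= 0.5 * peak) return(TRUE)
  }
  FALSE
}

#' Place field size
#'
#' Complete fields: distance between the two 15% threshold crossings.
#' Fields with a single detected end: twice the distance from the peak
#' to that end (slightly overestimates sizes of skewed fields, which is
#' conservative for the corner regions where such fields occur).
#'
#' @param field one row of [detect_fields()] output.
#' @return size (cm), or NA if neither end was detected.
#' @export
field_size <- function(field) {
  if (field$start_detected && field$end_detected) return(field$end - field$start)
  if (field$end_detected) return(2 * (field$end - field$peak_x))
  if (field$start_detected) return(2 * (field$peak_x - field$start))
  NA_real_
}

#' Sampling index of a field's occupancy
#'
#' Sum of pairwise bin distances between sufficiently occupied bins
#' within the field, divided by the sum over all bin pairs. Grows
#' nonlinearly from 0 (no valid bins) to 1 (all valid), rewarding both
#' the number of valid bins and their spread through the field.
#'
#' @param occupancy per-bin occupancy within the field extent (s), or a
#'   logical validity vector.
#' @param min_occ occupancy threshold (s), default 0.3.
#' @return fraction in \[0, 1\].
#' @export
sampling_index <- function(occupancy, min_occ = 0.3) {
  nb <- length(occupancy)
  if (nb < 2) return(as.numeric(nb > 0))
  valid <- which(as.numeric(occupancy) > min_occ)
  idx <- seq_len(nb)
  total <- sum(stats::dist(idx))
  if (length(valid) < 2) return(0)
  sum(stats::dist(valid)) / total
}

#' Place field skew
#'
#' Rate-weighted third standardized moment of the firing-rate
#' distribution over the spatial bins within the field extent.
#'
#' @param rate_map output of [compute_rate_map()].
#' @param start,end field extent (cm).
#' @return dimensionless skew.
#' @export
field_skew <- function(rate_map, start, end) {
  sel <- rate_map$bin_center >= start & rate_map$bin_center <= end
  f <- rate_map$rate[sel]
  x <- rate_map$bin_center[sel]
  w <- sum(f)
  if (w == 0) return(NA_real_)
  mu1 <- sum(f * x) / w
  sig <- sqrt(sum(f * (x - mu1)^2) / w)
  if (sig == 0) return(0)
  (sum(f * (x - mu1)^3) / w) / sig^3
}

#' Per-speed-bin place field sizes
#'
#' Recomputes the rate map restricted to each overlapping speed bin and
#' re-measures the field size within the extent of the all-speed field
#' (the reference region). A bin is measured only when its sampling
#' index within the extent reaches `min_sampling`; otherwise the size is
#' missing, never zero. Per-bin identification follows the all-speed
#' rules (peak at least 2 Hz, 25 spikes); a side whose 15% crossing does
#' not occur before the reference extent edge uses the doubling rule.
#'
#' @param field one row of [detect_fields()] output.
#' @param spike_x_by_bin list (over the 7 speed bins) of spike positions.
#' @param occ_x_by_bin list of included tracking positions per bin.
#' @param fs tracking sampling rate (Hz).
#' @param track_length track length (cm).
#' @param bin spatial bin width (cm).
#' @param min_sampling sampling-index threshold, default 0.4.
#' @return tibble with `bin`, `center`, `size`, `sampling_index`,
#'   `peak_rate`, `n_spikes`.
#' @export
sizes_by_speed <- function(field, spike_x_by_bin, occ_x_by_bin, fs,
                           track_length, bin = 4, min_sampling = 0.4) {
  sb <- speed_bins()
  purrr::map_dfr(seq_len(nrow(sb)), function(i) {
    res <- tibble::tibble(bin = sb$bin[i], center = sb$center[i],
                          size = NA_real_, sampling_index = NA_real_,
                          peak_rate = NA_real_, n_spikes = NA_integer_)
    occ_x <- occ_x_by_bin[[i]]
    if (length(occ_x) == 0) return(res)
    rm_i <- compute_rate_map(spike_x_by_bin[[i]], occ_x, fs, track_length,
                             bin = bin)
    sel <- rm_i$bin_center >= field$start & rm_i$bin_center <= field$end
    si <- sampling_index(rm_i$occupancy[sel])
    res$sampling_index <- si
    if (si < min_sampling) return(res)
    f2 <- measure_size_around_peak(rm_i, field$start, field$end)
    if (is.null(f2)) return(res)
    ns <- sum(spike_x_by_bin[[i]] >= field$start &
                spike_x_by_bin[[i]] <= field$end)
    res$n_spikes <- as.integer(ns)
    res$peak_rate <- f2$peak_rate
    if (f2$peak_rate >= 2 && ns >= 25) res$size <- f2$size
    res
  })
}

# size of the field on a (speed-restricted) map: the peak is taken
# within the reference extent, but the 15% crossings are searched on the
# full map, since the per-speed field may be narrower or wider than the
# all-speed one
measure_size_around_peak <- function(rate_map, start, end,
                                     thresh_frac = 0.15,
                                     max_zero_occ = 3) {
  r <- rate_map$rate
  centers <- rate_map$bin_center
  occ <- rate_map$occupancy
  nb <- length(r)
  sel <- which(centers >= start & centers <= end)
  if (length(sel) == 0) return(NULL)
  p <- sel[which.max(r[sel])]
  peak <- r[p]
  if (peak == 0) return(NULL)
  thr <- thresh_frac * peak
  jl <- p
  while (jl > 1 && r[jl - 1] >= thr) jl <- jl - 1
  sdet <- jl > 1 && max_zero_run(occ[jl:p]) <= max_zero_occ
  s <- if (jl > 1) cross_at(centers, r, jl - 1, thr, TRUE) else centers[1]
  jr <- p
  while (jr < nb && r[jr + 1] >= thr) jr <- jr + 1
  edet <- jr < nb && max_zero_run(occ[p:jr]) <= max_zero_occ
  e <- if (jr < nb) cross_at(centers, r, jr, thr, FALSE) else centers[nb]
  size <- if (sdet && edet) e - s
          else if (edet) 2 * (e - centers[p])
          else if (sdet) 2 * (centers[p] - s)
          else NA_real_
  list(size = size, peak_rate = peak)
}

#' Remove extreme outliers with Tukey fences
#'
#' Drops values below `Q1 - k IQR` or above `Q3 + k IQR`, with quartiles
#' from linearly interpolated (type-7) quantiles. `k = 3` is used for
#' field sizes and pooled slopes, `k = 6` for single-pass slopes.
#'
#' @param values numeric vector (NAs are dropped).
#' @param k fence multiplier.
#' @return filtered values, original order preserved.
#' @export
remove_outliers <- function(values, k = 3) {
  values <- values[!is.na(values)]
  if (length(values) < 4) return(values)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}
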