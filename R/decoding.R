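#' Theta-cycle decoding configuration
#'
#' @param window_deg phase window width (deg).
#' @param step_deg phase step between windows (deg).
#' @param spatial_window decoded extent centered on the current position
#'   (cm).
#' @param peak_floor minimum peak decoded probability for a phase bin to
#'   count as well decoded.
#' @param min_bins minimum number of qualifying phase bins per cycle.
#' @param min_span_deg minimum phase coverage of the qualifying bins
#'   (deg).
#' @param band_halfwidth half-width of the line-fit probability band
#'   (cm).
#' @param rate_floor rate floor (Hz) added inside the window to avoid
#'   zero-likelihood columns.
#' @param slope_grid candidate trajectory slopes (cm/s).
#' @param intercept_step intercept grid resolution (cm).
#' @return list of class `decoding_config`.
#' @export
decoding_config <- function(window_deg = 90, step_deg = 30,
                            spatial_window = 70, peak_floor = 0.1,
                            min_bins = 5, min_span_deg = 210,
                            band_halfwidth = 5, rate_floor = 1,
                            slope_grid = seq(-800, 800, by = 8),
                            intercept_step = 1) {
  structure(list(window_deg = window_deg, step_deg = step_deg,
                 spatial_window = spatial_window, peak_floor = peak_floor,
                 min_bins = min_bins, min_span_deg = min_span_deg,
                 band_halfwidth = band_halfwidth, rate_floor = rate_floor,
                 slope_grid = slope_grid, intercept_step = intercept_step),
            class = "decoding_config")
}

#' Bayesian position decoding of one time window
#'
#' Posterior over allowed positions given a spike-count vector, assuming
#' independent Poisson cells and a uniform prior over the window:
#' `P(x|n) = C prod_i f_i(x)^{n_i} exp(-tau sum_i f_i(x))`.
#'
#' @param n spike counts, one per cell.
#' @param rates matrix (positions x cells) of firing rates (Hz).
#' @param tau window duration (s).
#' @return probability vector over positions (sums to 1), or NULL if the
#'   likelihood is zero everywhere.
#' @export
decode_window <- function(n, rates, tau) {
  abort_if(sum(n) < 1, "decoding needs at least one spike")
  lograte <- log(rates)
  lograte[rates == 0] <- -Inf
  logp <- as.numeric(lograte %*% n) - tau * rowSums(rates)
  if (all(!is.finite(logp))) return(NULL)
  p <- exp(logp - max(logp[is.finite(logp)]))
  p[!is.finite(p)] <- 0
  s <- sum(p)
  if (s == 0) return(NULL)
  p / s
}

#' Decode one theta cycle in overlapping phase windows
#'
#' Phase windows of `window_deg` at `step_deg` steps fully inside the
#' cycle are converted to time intervals from the cycle's own period.
#' Position is decoded only in windows containing at least one spike,
#' over map bins within `spatial_window`/2 of the animal's position at
#' the cycle's temporal midpoint; the position axis is reported relative
#' to that reference.
#'
#' @param cycle one row of a cycle table (`start_t`, `end_t`, `period`).
#' @param spikes tibble with `cell`, `t`.
#' @param rates matrix (track bins x cells) of direction-specific rates.
#' @param bin_centers positions of the map bins (cm).
#' @param x0 the animal's position at the cycle midpoint (cm).
#' @param cfg a [decoding_config()].
#' @return object of class `posterior_matrix`: list with `P` (positions
#'   x windows; NA columns were not decoded), `rel_pos`, `t_rel`
#'   (window-center times relative to the cycle midpoint, s),
#'   `window_start_deg`, `tau`, `period`, `x0`.
#' @export
decode_cycle <- function(cycle, spikes, rates, bin_centers, x0, cfg) {
  T <- cycle$period
  starts_deg <- seq(0, 360 - cfg$window_deg, by = cfg$step_deg)
  tau <- cfg$window_deg / 360 * T
  allowed <- which(abs(bin_centers - x0) <= cfg$spatial_window / 2)
  sub <- rates[allowed, , drop = FALSE] + cfg$rate_floor
  P <- matrix(NA_real_, nrow = length(allowed), ncol = length(starts_deg))
  in_cycle <- spikes$t >= cycle$start_t & spikes$t < cycle$end_t
  st <- spikes$t[in_cycle]
  sc <- spikes$cell[in_cycle]
  ncells <- ncol(rates)
  for (w in seq_along(starts_deg)) {
    t0 <- cycle$start_t + starts_deg[w] / 360 * T
    t1 <- t0 + tau
    inw <- st >= t0 & st < t1
    if (!any(inw)) next
    nvec <- tabulate(sc[inw], nbins = ncells)
    p <- decode_window(nvec, sub, tau)
    if (!is.null(p)) P[, w] <- p
  }
  t_mid <- cycle$start_t + T / 2
  structure(list(P = P, rel_pos = bin_centers[allowed] - x0,
                 t_rel = cycle$start_t + (starts_deg + cfg$window_deg / 2) /
                   360 * T - t_mid,
                 window_start_deg = starts_deg, tau = tau, period = T,
                 x0 = x0), class = "posterior_matrix")
}

#' Is a decoded cycle well covered?
#'
#' Requires at least `min_bins` decoded phase bins whose peak decoded
#' probability exceeds `peak_floor`, together covering at least
#' `min_span_deg` of phase (from the start of the first qualifying
#' window to the end of the last).
#'
#' @param pm a `posterior_matrix`.
#' @param cfg a [decoding_config()].
#' @return logical.
#' @export
cycle_ok <- function(pm, cfg) {
  peaks <- suppressWarnings(apply(pm$P, 2, max, na.rm = TRUE))
  good <- is.finite(peaks) & peaks > cfg$peak_floor
  if (sum(good) < cfg$min_bins) return(FALSE)
  span <- max(pm$window_start_deg[good]) + cfg$window_deg -
    min(pm$window_start_deg[good])
  span >= cfg$min_span_deg
}

#' Fit a theta trajectory to a decoded cycle
#'
#' First finds, by grid search, the line (over time within the cycle)
#' that maximizes the sum of decoded probabilities within
#' `band_halfwidth` cm of the line; then refits by linear regression of
#' position on time using the in-band points weighted by their
#' probabilities. The signed trajectory length is the refitted slope
#' times the full cycle period, positive when the trajectory runs in the
#' direction of motion.
#'
#' @param pm a `posterior_matrix`.
#' @param direction "right" or "left" (sign convention).
#' @param cfg a [decoding_config()].
#' @return tibble with `slope` (cm/s), `length` (cm), `band_mass`,
#'   `n_bins`; NULL for degenerate (single-column) matrices.
#' @export
fit_trajectory <- function(pm, direction, cfg) {
  decoded <- which(colSums(is.finite(pm$P)) > 0)
  if (length(decoded) < 2) return(NULL)
  P <- pm$P[, decoded, drop = FALSE]
  tt <- pm$t_rel[decoded]
  pos <- pm$rel_pos
  half <- cfg$spatial_window / 2
  intercepts <- seq(-half, half, by = cfg$intercept_step)
  bw <- cfg$band_halfwidth
  nI <- length(intercepts)
  # treat each column as a piecewise-uniform density over its 4 cm bins,
  # so the band mass varies smoothly with the line (no whole-bin capture
  # artifacts at the band edges)
  binw <- if (length(pos) > 1) pos[2] - pos[1] else 1
  edges <- c(pos - binw / 2, pos[length(pos)] + binw / 2)
  nb <- length(pos)
  # precompute, per column, the band mass at 1 cm line offsets; the grid
  # search then reduces to integer-shifted lookups
  max_shift <- max(abs(cfg$slope_grid)) * max(abs(tt)) + half + bw + 2
  ugrid <- seq(-ceiling(max_shift), ceiling(max_shift), by = 1)
  nu <- length(ugrid)
  bandmass <- matrix(0, nrow = nu, ncol = length(tt))
  for (c in seq_along(tt)) {
    m <- ifelse(is.finite(P[, c]), P[, c], 0)
    cs <- c(0, cumsum(m))
    cum_at <- function(q) {
      j <- findInterval(q, edges)
      out <- ifelse(j < 1, 0, cs[pmin(j, nb) + 1L])
      inside <- which(j >= 1 & j <= nb)
      out[inside] <- cs[j[inside]] + m[j[inside]] *
        (q[inside] - edges[j[inside]]) / binw
      out
    }
    bandmass[, c] <- cum_at(ugrid + bw) - cum_at(ugrid - bw)
  }
  i0 <- round(intercepts - ugrid[1]) + 1L
  best <- c(score = -Inf, slope = NA, intercept = NA)
  for (a in cfg$slope_grid) {
    score <- numeric(nI)
    for (c in seq_along(tt)) {
      score <- score + bandmass[i0 + round(a * tt[c]), c]
    }
    m <- which.max(score)
    if (score[m] > best["score"]) {
      best <- c(score = score[m], slope = a, intercept = intercepts[m])
    }
  }
  if (!is.finite(best["score"])) return(NULL)
  # weighted regression on in-band points
  grid_t <- rep(tt, each = length(pos))
  grid_x <- rep(pos, times = length(tt))
  w <- as.numeric(P)
  w[!is.finite(w)] <- 0
  inband <- abs(grid_x - (best["slope"] * grid_t + best["intercept"])) <= bw &
    w > 0
  if (!any(inband) || length(unique(grid_t[inband])) < 2) return(NULL)
  wt <- w[inband]; xt <- grid_t[inband]; yt <- grid_x[inband]
  wm_x <- sum(wt * xt) / sum(wt)
  wm_y <- sum(wt * yt) / sum(wt)
  denom <- sum(wt * (xt - wm_x)^2)
  if (denom == 0) return(NULL)
  slope <- sum(wt * (xt - wm_x) * (yt - wm_y)) / denom
  sgn <- if (direction == "left") -1 else 1
  tibble::tibble(slope = slope, length = sgn * slope * pm$period,
                 band_mass = unname(best["score"]),
                 n_bins = length(decoded))
}

#' Decode all significant theta cycles of a session
#'
#' @param spikes tibble with `cell`, `t`.
#' @param cycles cycle table from [segment_cycles()].
#' @param tracking annotated tracking tibble.
#' @param rate_maps named list (`right`, `left`) of rate matrices
#'   (track bins x cells).
#' @param bin_centers positions of the map bins (cm).
#' @param cfg a [decoding_config()].
#' @return tibble with one row per analyzable cycle: `cycle`, `t_mid`,
#'   `x0`, `v_mid`, `direction`, `ok`, `slope`, `length`, `n_bins`,
#'   plus a list column `pm` with the posterior matrices.
#' @export
decode_session_cycles <- function(spikes, cycles, tracking, rate_maps,
                                  bin_centers, cfg = decoding_config()) {
  cyc <- cycles[cycles$significant, ]
  t_mid <- (cyc$start_t + cyc$end_t) / 2
  x0 <- interp1(tracking$t, tracking$x, t_mid)
  v0 <- abs(interp1(tracking$t, tracking$v, t_mid))
  dir0 <- run_direction_at(tracking, t_mid)
  keep <- !is.na(dir0)
  purrr::map_dfr(which(keep), function(i) {
    pm <- decode_cycle(cyc[i, ], spikes, rate_maps[[dir0[i]]],
                       bin_centers, x0[i], cfg)
    ok <- cycle_ok(pm, cfg)
    fit <- if (ok) fit_trajectory(pm, dir0[i], cfg) else NULL
    tibble::tibble(cycle = cyc$cycle[i], t_mid = t_mid[i], x0 = x0[i],
                   v_mid = v0[i], direction = dir0[i], ok = ok,
                   slope = if (is.null(fit)) NA_real_ else fit$slope,
                   length = if (is.null(fit)) NA_real_ else fit$length,
                   n_bins = sum(colSums(is.finite(pm$P)) > 0),
                   pm = list(pm))
  })
}

run_direction_at <- function(tracking, t) {
  idx <- pmin(pmax(round(interp1(tracking$t, seq_len(nrow(tracking)), t)),
                   1L), nrow(tracking))
  d <- tracking$direction[idx]
  d[d == "pause"] <- NA_character_
  d
}

#' Average decoded posteriors by speed bin and refit trajectories
#'
#' Element-wise mean of the aligned relative-position posterior matrices
#' over all cycles whose midpoint speed lies in each overlapping speed
#' bin; a trajectory is fitted to the average. Lengths are reported only
#' for bins with more than `min_cycles` cycles.
#'
#' @param decoded output of [decode_session_cycles()].
#' @param cfg a [decoding_config()].
#' @param min_cycles minimum cycles per bin (exclusive), default 5.
#' @return tibble with `bin`, `center`, `n_cycles`, `length`.
#' @export
average_posteriors_by_speed <- function(decoded, cfg = decoding_config(),
                                        min_cycles = 5) {
  sb <- speed_bins()
  purrr::map_dfr(seq_len(nrow(sb)), function(i) {
    sel <- decoded[decoded$v_mid >= sb$lo[i] & decoded$v_mid < sb$hi[i] &
                     decoded$ok, ]
    if (nrow(sel) <= min_cycles) {
      return(tibble::tibble(bin = sb$bin[i], center = sb$center[i],
                            n_cycles = nrow(sel), length = NA_real_))
    }
    pms <- sel$pm
    nr <- max(vapply(pms, function(p) length(p$rel_pos), integer(1)))
    full <- vapply(pms, function(p) length(p$rel_pos) == nr, logical(1))
    pms <- pms[full]
    # flip leftward cycles so "ahead of the animal" is always positive
    arr <- lapply(seq_along(pms), function(k) {
      P <- pms[[k]]$P
      if (sel$direction[full][k] == "left") P <- P[nrow(P):1, , drop = FALSE]
      P
    })
    Pbar <- Reduce(`+`, lapply(arr, function(P) ifelse(is.finite(P), P, 0)))
    Nbar <- Reduce(`+`, lapply(arr, function(P) is.finite(P) + 0))
    Pavg <- ifelse(Nbar > 0, Pbar / Nbar, NA_real_)
    ref <- pms[[1]]
    Tbar <- mean(vapply(pms, function(p) p$period, numeric(1)))
    pm_avg <- structure(list(P = Pavg, rel_pos = ref$rel_pos,
                             t_rel = (ref$window_start_deg +
                                        cfg$window_deg / 2) / 360 * Tbar -
                               Tbar / 2,
                             window_start_deg = ref$window_start_deg,
                             tau = cfg$window_deg / 360 * Tbar,
                             period = Tbar, x0 = 0),
                        class = "posterior_matrix")
    fit <- fit_trajectory(pm_avg, "right", cfg)
    tibble::tibble(bin = sb$bin[i], center = sb$center[i],
                   n_cycles = nrow(sel),
                   length = if (is.null(fit)) NA_real_ else fit$length)
  })
}
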