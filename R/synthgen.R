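#' Linear track configuration
#'
#' @param length track length (cm).
#' @param spatial_bin spatial bin width used downstream (cm).
#' @param n_runs_per_direction number of corner-to-corner runs in each
#'   direction.
#' @param pause_range range (s) of the uniform pause duration at each
#'   corner between runs.
#' @param tracking_fs position sampling rate (Hz).
#' @return object of class `track_config`.
#' @export
track_config <- function(length = 240, spatial_bin = 4,
                         n_runs_per_direction = 12,
                         pause_range = c(1, 3), tracking_fs = 40) {
  abort_if(length <= 0, "track length must be positive")
  abort_if(n_runs_per_direction < 1, "need at least one run per direction")
  structure(list(length = length, spatial_bin = spatial_bin,
                 n_runs_per_direction = n_runs_per_direction,
                 pause_range = pause_range, tracking_fs = tracking_fs),
            class = "track_config")
}

#' Theta sweep scheme parameters
#'
#' The three generative coding schemes relate the represented position
#' r(t) to the animal's location x(t) and theta phase:
#' spatial `r = x + d_theta (theta - theta0)/360`; temporal
#' `r = x(t + tau_theta (theta - theta0)/360)`; behavior-dependent
#' `r = x + vbar(x) tau_theta (theta - theta0)/360`.
#'
#' @param scheme "spatial", "temporal" or "behavior".
#' @param d_theta theta distance (cm); spatial scheme only.
#' @param tau_theta look-ahead time (s); temporal and behavior schemes.
#' @param theta0 phase (deg) at which the population represents the
#'   actual position; default 180.
#' @return object of class `sweep_params`.
#' @export
sweep_params <- function(scheme = c("spatial", "temporal", "behavior"),
                         d_theta = NULL, tau_theta = NULL, theta0 = 180) {
  scheme <- match.arg(scheme)
  abort_if(theta0 < 0 || theta0 >= 360, "theta0 must lie in [0, 360)")
  if (scheme == "spatial") {
    abort_if(is.null(d_theta), "spatial scheme requires d_theta")
    abort_if(!is.null(tau_theta), "spatial scheme takes d_theta, not tau_theta")
  } else {
    abort_if(is.null(tau_theta), paste0(scheme, " scheme requires tau_theta"))
    abort_if(!is.null(d_theta), paste0(scheme, " scheme takes tau_theta, not d_theta"))
  }
  structure(list(scheme = scheme, d_theta = d_theta, tau_theta = tau_theta,
                 theta0 = theta0, alpha = theta0 / 360),
            class = "sweep_params")
}

#' Poisson spiking parameters
#'
#' Per-2-ms-bin spike probability:
#' `P = [rate_base + rate_speed_gain * v] [1 - m_theta cos(theta)] f(r) dt`,
#' where `f(r)` is the cell's Gaussian true-field activation (peak 1).
#'
#' @param rate_base baseline peak rate (Hz), default 15.
#' @param rate_speed_gain rate increase per cm/s of running speed
#'   (Hz s/cm), default 0.2.
#' @param m_theta depth of the theta amplitude modulation, default 0.35.
#' @param dt simulation time bin (s), default 0.002.
#' @return object of class `spiking_params`.
#' @export
spiking_params <- function(rate_base = 15, rate_speed_gain = 0.2,
                           m_theta = 0.35, dt = 0.002) {
  abort_if(m_theta < 0 || m_theta >= 1, "m_theta must lie in [0, 1)")
  structure(list(rate_base = rate_base, rate_speed_gain = rate_speed_gain,
                 m_theta = m_theta, dt = dt), class = "spiking_params")
}

#' Characteristic-speed profile for session generation
#'
#' An asymmetric inverted-U profile built from two half-cosines: speed is
#' `end_speed` at both corners and rises smoothly to `peak_speed` at a
#' position displaced toward the first half of the run (rats accelerate
#' out of the start corner faster than they brake into the far one). The
#' leftward profile mirrors the rightward one.
#'
#' @param track a [track_config()].
#' @param peak_speed maximum characteristic speed (cm/s).
#' @param asymmetry peak displacement, 0 (symmetric) to 0.5; the peak
#'   sits at a fraction `0.5 - 0.5 * asymmetry` of the run.
#' @param end_speed characteristic speed at the corners (cm/s).
#' @return tibble with `direction`, `bin_left`, `bin_center`, `vbar`.
#' @export
make_characteristic_profile <- function(track, peak_speed = 60,
                                        asymmetry = 0.25, end_speed = 5) {
  abort_if(peak_speed <= 0, "peak_speed must be positive")
  L <- track$length
  b <- track$spatial_bin
  centers <- seq(0, L - b, by = b) + b / 2
  u <- centers / L
  u_pk <- 0.5 - 0.5 * asymmetry
  bump <- ifelse(u <= u_pk,
                 (1 - cos(pi * u / u_pk)) / 2,
                 (1 - cos(pi * (1 - u) / (1 - u_pk))) / 2)
  v_right <- end_speed + (peak_speed - end_speed) * bump
  dplyr::bind_rows(
    tibble::tibble(direction = "right", bin_left = centers - b / 2,
                   bin_center = centers, vbar = v_right),
    tibble::tibble(direction = "left", bin_left = centers - b / 2,
                   bin_center = centers, vbar = rev(v_right))
  )
}

#' Generate a corner-to-corner running trajectory
#'
#' Alternating rightward and leftward runs with pauses at the corners.
#' Within each run the instantaneous speed is the characteristic speed at
#' the current position times a per-run lognormal factor with coefficient
#' of variation `run_speed_cv` (speeds cluster around the characteristic
#' profile run to run).
#'
#' @param track a [track_config()].
#' @param profile characteristic-speed profile covering both directions.
#' @param run_speed_cv coefficient of variation of the per-run speed
#'   multiplier (0 = every run exactly on the profile).
#' @param seed optional RNG seed.
#' @return tibble with `t`, `x`, `direction`, `run_id` sampled at the
#'   tracking rate.
#' @export
generate_trajectory <- function(track, profile, run_speed_cv = 0.15,
                                seed = NULL) {
  abort_if(run_speed_cv < 0, "run_speed_cv must be non-negative")
  abort_if(max(profile$bin_center) > track$length ||
             max(profile$bin_center) < track$length - 2 * track$spatial_bin,
           "profile does not match track length")
  if (!is.null(seed)) set.seed(seed)
  L <- track$length
  dt <- 1 / track$tracking_fs
  sdlog <- sqrt(log(1 + run_speed_cv^2))
  n_runs <- 2L * track$n_runs_per_direction
  xs <- list(); dirs <- list(); rids <- list()
  x_cur <- 0
  pr <- profile[profile$direction == "right", ]
  pl <- profile[profile$direction == "left", ]
  for (r in seq_len(n_runs)) {
    # pause at the corner before each run
    pause <- runif(1, track$pause_range[1], track$pause_range[2])
    np <- max(1L, round(pause / dt))
    xs[[length(xs) + 1L]] <- rep(x_cur, np)
    dirs[[length(dirs) + 1L]] <- rep("pause", np)
    rids[[length(rids) + 1L]] <- rep(NA_integer_, np)
    rightward <- x_cur < L / 2
    p <- if (rightward) pr else pl
    k <- if (run_speed_cv > 0) rlnorm(1, -sdlog^2 / 2, sdlog) else 1
    x_run <- numeric(ceiling(4 * L / (5 * dt)))  # generous buffer
    i <- 0L
    x <- x_cur
    repeat {
      v <- interp1(p$bin_center, p$vbar, x) * k
      x <- x + (if (rightward) v else -v) * dt
      if ((rightward && x >= L) || (!rightward && x <= 0)) break
      i <- i + 1L
      x_run[i] <- x
    }
    x_end <- if (rightward) L else 0
    x_run <- c(x_run[seq_len(i)], x_end)
    xs[[length(xs) + 1L]] <- x_run
    dirs[[length(dirs) + 1L]] <- rep(if (rightward) "right" else "left",
                                     length(x_run))
    rids[[length(rids) + 1L]] <- rep(r, length(x_run))
    x_cur <- x_end
  }
  x <- unlist(xs)
  tibble::tibble(
    t = (seq_along(x) - 1L) * dt,
    x = x,
    direction = unlist(dirs),
    run_id = unlist(rids)
  )
}

#' Generate a theta phase series and cosine-locked LFP
#'
#' Per-cycle frequencies are drawn from a lognormal distribution with the
#' requested mean and coefficient of variation; phase rises linearly from
#' 0 to 360 degrees within each cycle. The emitted LFP is `cos(phase)`,
#' so LFP peaks sit at 0/360 degrees and troughs at 180 degrees.
#'
#' @param duration series duration (s).
#' @param mean_freq mean theta frequency (Hz), default 8.
#' @param cycle_jitter_cv coefficient of variation of per-cycle frequency
#'   (0 = perfectly regular oscillation).
#' @param fs sampling rate of the emitted series (Hz).
#' @param seed optional RNG seed.
#' @return object of class `theta_series`: list with `samples`
#'   (tibble `t`, `phase`, `lfp`), `cycles` (tibble `cycle`, `start_t`,
#'   `end_t`, `period`) and `fs`.
#' @export
generate_theta_phase <- function(duration, mean_freq = 8,
                                 cycle_jitter_cv = 0, fs = 250, seed = NULL) {
  abort_if(duration <= 0, "duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_guess <- ceiling(duration * mean_freq * 1.5) + 10L
  if (cycle_jitter_cv > 0) {
    sdlog <- sqrt(log(1 + cycle_jitter_cv^2))
    freqs <- rlnorm(n_guess, log(mean_freq) - sdlog^2 / 2, sdlog)
  } else {
    freqs <- rep(mean_freq, n_guess)
  }
  periods <- 1 / freqs
  starts <- c(0, cumsum(periods))
  n_cyc <- which(starts >= duration)[1] - 1L
  starts <- starts[seq_len(n_cyc + 1L)]
  t <- seq(0, duration, by = 1 / fs)
  idx <- pmin(pmax(findInterval(t, starts), 1L), n_cyc)
  phase <- 360 * (t - starts[idx]) / periods[idx]
  phase <- pmin(phase, 360 - 1e-9) %% 360
  structure(list(
    samples = tibble::tibble(t = t, phase = phase,
                             lfp = cos(deg2rad(phase))),
    cycles = tibble::tibble(cycle = seq_len(n_cyc),
                            start_t = starts[-length(starts)],
                            end_t = starts[-1],
                            period = periods[seq_len(n_cyc)]),
    fs = fs), class = "theta_series")
}

#' Evaluate theta phase at arbitrary times
#'
#' @param theta a `theta_series`.
#' @param t times (s); clamped to the series span.
#' @return phase in degrees, \[0, 360).
#' @export
theta_phase_at <- function(theta, t) {
  cyc <- theta$cycles
  t <- pmin(pmax(t, cyc$start_t[1]), cyc$end_t[nrow(cyc)] - 1e-9)
  idx <- pmin(pmax(findInterval(t, cyc$start_t), 1L), nrow(cyc))
  (360 * (t - cyc$start_t[idx]) / cyc$period[idx]) %% 360
}

#' Represented position under a sweep scheme
#'
#' Maps the animal's location and the instantaneous theta phase to the
#' position represented by the place-cell population. For the temporal
#' scheme the represented position is the trajectory position at the
#' phase-shifted time (clamped to the session span); for the
#' behavior-dependent scheme the sweep extent is the characteristic speed
#' at the current location times the look-ahead time. The result is
#' clipped to the track extent.
#'
#' @param x positions (cm).
#' @param theta_phase phases (deg, \[0,360)).
#' @param params a [sweep_params()].
#' @param track_length track length (cm) for clipping.
#' @param vbar characteristic speeds at `x` (behavior scheme only).
#' @param trajectory tibble `t`, `x` (temporal scheme only).
#' @param t times of each sample (temporal scheme only).
#' @param heading +1 for rightward travel, -1 for leftward; the sweep
#'   runs from behind to ahead of the animal, so its sign follows the
#'   direction of motion (the temporal scheme inherits it from the
#'   trajectory itself). With a common heading the three schemes agree
#'   on constant-speed segments when `d_theta = vbar tau_theta =
#'   v tau_theta`.
#' @return represented positions r (cm).
#' @export
represented_position <- function(x, theta_phase, params, track_length,
                                 vbar = NULL, trajectory = NULL, t = NULL,
                                 heading = 1) {
  frac <- (theta_phase - params$theta0) / 360
  r <- switch(params$scheme,
    spatial = x + heading * params$d_theta * frac,
    temporal = {
      abort_if(is.null(trajectory) || is.null(t),
               "temporal scheme needs the trajectory and sample times")
      interp1(trajectory$t, trajectory$x, t + params$tau_theta * frac)
    },
    behavior = {
      abort_if(is.null(vbar), "behavior scheme needs characteristic speeds")
      x + heading * vbar * params$tau_theta * frac
    })
  pmin(pmax(r, 0), track_length)
}

#' Per-bin spike probability of a place cell
#'
#' @param center,sigma true-field center (cm) and width (cm).
#' @param r represented positions (cm).
#' @param v instantaneous running speeds (cm/s), non-negative.
#' @param theta_phase phases (deg).
#' @param sp a [spiking_params()].
#' @param f_max peak activation, default 1.
#' @return probability of a spike in one time bin, clamped to \[0, 1\].
#' @export
spike_probability <- function(center, sigma, r, v, theta_phase, sp,
                              f_max = 1) {
  abort_if(any(v < 0), "speeds must be non-negative")
  act <- f_max * exp(-(r - center)^2 / (2 * sigma^2))
  p <- (sp$rate_base + sp$rate_speed_gain * v) *
    (1 - sp$m_theta * cos(deg2rad(theta_phase))) * act * sp$dt
  pmin(pmax(p, 0), 1)
}

#' Simulate a complete linear-track session
#'
#' Generates a trajectory, a theta series, and spikes from `n_cells`
#' place cells with true fields uniformly distributed along the track,
#' using an inhomogeneous Bernoulli approximation of a Poisson process in
#' 2 ms time bins. True-field widths are 7 cm for the spatial and
#' temporal schemes; for the behavior-dependent scheme they are
#' heterogeneous, `max(4, 0.3 * vbar(center) * tau_theta)`.
#'
#' @param track a [track_config()].
#' @param params a [sweep_params()].
#' @param profile characteristic-speed profile; defaults to
#'   [make_characteristic_profile()].
#' @param n_cells number of simulated place cells.
#' @param sp a [spiking_params()].
#' @param run_speed_cv per-run speed variability (see
#'   [generate_trajectory()]).
#' @param cycle_jitter_cv theta cycle variability (see
#'   [generate_theta_phase()]).
#' @param theta_fs LFP/phase sampling rate (Hz).
#' @param sigma optional true-field width override (cm), scalar or
#'   per-cell vector.
#' @param seed RNG seed; fixed seeds give identical sessions.
#' @return object of class `theta_session`: list with `tracking`,
#'   `theta`, `spikes` (tibble `cell`, `t`), `truth` and `track`.
#' @export
generate_session <- function(track, params,
                             profile = make_characteristic_profile(track),
                             n_cells = 20, sp = spiking_params(),
                             run_speed_cv = 0.15, cycle_jitter_cv = 0.1,
                             theta_fs = 250, sigma = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- track$length
  tracking <- generate_trajectory(track, profile, run_speed_cv)
  duration <- max(tracking$t) + 1 / track$tracking_fs
  theta <- generate_theta_phase(duration, mean_freq = 8,
                                cycle_jitter_cv = cycle_jitter_cv,
                                fs = theta_fs)
  centers <- (seq_len(n_cells) - 0.5) * L / n_cells
  vbar_at_center <- (profile_speed_at(profile, centers, "right") +
                       profile_speed_at(profile, centers, "left")) / 2
  if (is.null(sigma)) {
    sigma <- if (params$scheme == "behavior") {
      pmax(4, 0.3 * vbar_at_center * params$tau_theta)
    } else 7
  }
  sigma <- rep(sigma, length.out = n_cells)

  tg <- seq(0, max(tracking$t), by = sp$dt)
  xg <- interp1(tracking$t, tracking$x, tg)
  vtrack <- abs(compute_speed(tracking$x, track$tracking_fs))
  vg <- pmax(interp1(tracking$t, vtrack, tg), 0)
  phg <- theta_phase_at(theta, tg)
  # carry the most recent run direction through pauses for the vbar lookup
  dir_num <- ifelse(tracking$direction == "right", 1,
                    ifelse(tracking$direction == "left", -1, NA))
  dir_num <- fill_forward(dir_num, default = 1)
  heading <- interp_nearest(tracking$t, dir_num, tg)
  dirg <- ifelse(heading > 0, "right", "left")
  vbarg <- if (params$scheme == "behavior") {
    profile_speed_at(profile, xg, dirg)
  } else NULL
  r <- represented_position(xg, phg, params, L, vbar = vbarg,
                            trajectory = tracking, t = tg,
                            heading = heading)

  env <- (sp$rate_base + sp$rate_speed_gain * vg) *
    (1 - sp$m_theta * cos(deg2rad(phg))) * sp$dt
  spikes <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    p <- env * exp(-(r - centers[i])^2 / (2 * sigma[i]^2))
    abort_if(any(p > 1), "spike probability exceeded 1; reduce dt")
    hit <- which(runif(length(p)) < p)
    spikes[[i]] <- tibble::tibble(cell = i, t = tg[hit])
  }
  spikes <- dplyr::bind_rows(spikes)
  structure(list(
    tracking = tracking, theta = theta, spikes = spikes,
    truth = list(params = params, centers = centers, sigma = sigma,
                 spiking = sp, profile = profile,
                 run_speed_cv = run_speed_cv,
                 cycle_jitter_cv = cycle_jitter_cv, seed = seed),
    track = track), class = "theta_session")
}

#' Schematic constant-speed session
#'
#' Constant-speed runs with a jitter-free 8 Hz theta oscillation, used to
#' validate the pipeline against the closed-form predictions of each
#' scheme. Defaults: `tau_theta = 0.5` s (temporal/behavior),
#' `sigma = 6` cm.
#'
#' @param v_const running speed (cm/s).
#' @param params a [sweep_params()]; defaults to a spatial sweep with
#'   `d_theta = 30` cm.
#' @param track a [track_config()].
#' @param n_cells number of cells.
#' @param sigma true-field width (cm).
#' @param sp a [spiking_params()].
#' @param seed RNG seed.
#' @return a `theta_session`.
#' @export
schematic_session <- function(v_const,
                              params = sweep_params("spatial", d_theta = 30),
                              track = track_config(n_runs_per_direction = 6),
                              n_cells = 20, sigma = 6,
                              sp = spiking_params(), seed = NULL) {
  abort_if(v_const <= 0, "v_const must be positive")
  b <- track$spatial_bin
  centers <- seq(0, track$length - b, by = b) + b / 2
  flat <- dplyr::bind_rows(
    tibble::tibble(direction = "right", bin_left = centers - b / 2,
                   bin_center = centers, vbar = v_const),
    tibble::tibble(direction = "left", bin_left = centers - b / 2,
                   bin_center = centers, vbar = v_const))
  generate_session(track, params, profile = flat, n_cells = n_cells,
                   sp = sp, run_speed_cv = 0, cycle_jitter_cv = 0,
                   sigma = sigma, seed = seed)
}

fill_forward <- function(x, default = NA) {
  if (is.na(x[1])) x[1] <- default
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  idx[idx == 0L] <- 1L
  x[idx]
}

interp_nearest <- function(x, y, xout) {
  idx <- pmin(pmax(round(stats::approx(x, seq_along(x), xout = xout,
                                       rule = 2)$y), 1L), length(x))
  y[idx]
}
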