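# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small behavior-scheme session and its analysis (no decoding)
small_behavior_analysis <- function() {
  fixture("small_behavior", function() {
    sess <- generate_session(
      track_config(length = 200, n_runs_per_direction = 8),
      sweep_params("behavior", tau_theta = 0.57),
      n_cells = 14, seed = 101)
    list(session = sess,
         analysis = analyze_session(sess, optimize_offset = FALSE))
  })
}

# three default-configuration behavior-scheme sessions, analyzed
acceptance_behavior <- function() {
  fixture("acceptance_behavior", function() {
    lapply(1:3, function(s) {
      sess <- generate_session(track_config(),
                               sweep_params("behavior", tau_theta = 0.57),
                               n_cells = 20, seed = 1000 + s)
      analyze_session(sess, decode = FALSE)
    })
  })
}

# an analytic Gaussian rate map (no smoothing artifacts), for field
# detection oracles
gaussian_rate_map <- function(peak_x = 120, sigma = 7, peak_rate = 10,
                              track_length = 240, bin = 4,
                              occupancy = 1) {
  centers <- seq(bin / 2, track_length - bin / 2, by = bin)
  rate <- peak_rate * exp(-(centers - peak_x)^2 / (2 * sigma^2))
  tibble::tibble(
    bin_left = centers - bin / 2, bin_center = centers,
    occupancy = occupancy, count = 0, rate_raw = rate, rate = rate)
}

# exact points on a (possibly wrapped) precession line
line_cloud <- function(slope, intercept, n = 60, wrap = TRUE,
                       x = seq(0, 1, length.out = n)) {
  y <- slope * x + intercept
  if (wrap) y <- y %% 1
  tibble::tibble(position_norm = x, phase_norm = y)
}

# brute-force wrapped-ODR objective minimizer (independent oracle)
odr_grid_oracle <- function(cloud, slopes = seq(-6, 2, by = 0.01),
                            intercepts = seq(-1, 4, by = 0.01)) {
  x <- cloud$position_norm; y <- cloud$phase_norm
  obj <- function(a, b) {
    d0 <- (a * x + b - y)^2 / (1 + a^2)
    dup <- ifelse(y < 0.3, (a * x + b - (y + 1))^2 / (1 + a^2), Inf)
    ddn <- ifelse(y > 0.7, (a * x + b - (y - 1))^2 / (1 + a^2), Inf)
    sum(pmin(d0, pmin(dup, ddn)))
  }
  best <- c(Inf, NA, NA)
  for (a in slopes) {
    for (b in intercepts) {
      v <- obj(a, b)
      if (v < best[1]) best <- c(v, a, b)
    }
  }
  list(objective = best[1], slope = best[2], intercept = best[3])
}

# closed-form total least squares (minor axis) oracle
tls_oracle <- function(x, y) {
  cv <- stats::cov(cbind(x, y))
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  slope <- v[2] / v[1]
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}
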