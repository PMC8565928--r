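make_pm <- function(P, T = 0.125, rel = NULL) {
  n <- nrow(P)
  rel <- rel %||% (seq_len(n) - (n + 1) / 2) * 4
  starts <- seq(0, by = 30, length.out = ncol(P))
  structure(list(P = P, rel_pos = rel,
                 t_rel = (starts + 45) / 360 * T - T / 2,
                 window_start_deg = starts, tau = T / 4, period = T,
                 x0 = 0), class = "posterior_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("window decoding matches brute-force evaluation of the posterior formula", {
  pos <- seq(2, 70, by = 4)
  # two Gaussian-tuned cells
  rates <- cbind(10 * exp(-(pos - 20)^2 / (2 * 36)),
                 8 * exp(-(pos - 50)^2 / (2 * 64))) + 1
  tau <- 0.014
  p <- decode_window(c(1, 0), rates, tau)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # brute force: C * prod f^n * exp(-tau sum f)
  brute <- rates[, 1]^1 * rates[, 2]^0 * exp(-tau * rowSums(rates))
  brute <- brute / sum(brute)
  expect_lt(max(abs(p - brute)), 1e-10)
  expect_equal(which.max(p), which.max(brute))
  # uniform rates give a uniform posterior
  u <- decode_window(c(2, 1), matrix(5, 10, 2), tau)
  expect_equal(u, rep(0.1, 10), tolerance = 1e-12)
  expect_error(decode_window(c(0, 0), rates, tau), "at least one spike")
})

test_that("cycles decode in ten 90-degree windows converted to time", {
  cycle <- tibble::tibble(start_t = 1, end_t = 1.125, period = 0.125)
  pos <- seq(2, 238, by = 4)
  rates <- matrix(5, length(pos), 3)
  spikes <- tibble::tibble(cell = c(1L, 2L), t = c(1.01, 1.06))
  pm <- decode_cycle(cycle, spikes, rates, pos, x0 = 120,
                     cfg = decoding_config())
  expect_equal(length(pm$window_start_deg), 10)
  expect_equal(pm$tau, 0.125 / 4)
  # spike at 1.01 (phase 28.8) falls in windows starting 0; spike at
  # 1.06 (172.8) in windows starting 90, 120, 150
  decoded <- which(colSums(is.finite(pm$P)) > 0)
  expect_true(1 %in% decoded && all(c(4, 5, 6) %in% decoded))
  # no spikes at all: nothing decoded
  pm0 <- decode_cycle(cycle, spikes[0, ], rates, pos, 120,
                      decoding_config())
  expect_equal(sum(colSums(is.finite(pm0$P)) > 0), 0)
})

test_that("cycle quality needs five confident bins spanning 210 degrees", {
  cfg <- decoding_config()
  mk <- function(cols) {
    P <- matrix(NA_real_, 18, 10)
    for (c in cols) { P[, c] <- 0.01; P[9, c] <- 0.5 }
    make_pm(P)
  }
  expect_false(cycle_ok(mk(1:4), cfg))            # four bins
  expect_true(cycle_ok(mk(1:5), cfg))             # five bins covering 210
  expect_true(cycle_ok(mk(c(1, 3, 5, 7, 9, 10)), cfg))
  # five confident bins but diffuse columns fail the 0.1 peak rule
  Pd <- matrix(NA_real_, 18, 10)
  for (c in 1:5) Pd[, c] <- 1 / 18
  expect_false(cycle_ok(make_pm(Pd), cfg))
})

test_that("trajectory fits recover a linear ridge and its signed length", {
  cfg <- decoding_config()
  rel <- (seq_len(18) - 9.5) * 4
  tt <- (seq(0, 270, 30) + 45) / 360 * 0.125 - 0.125 / 2
  P <- sapply(tt, function(t) {
    d <- dnorm(rel, 240 * t, 4); d / sum(d)
  })
  f <- fit_trajectory(make_pm(P), "right", cfg)
  expect_equal(f$length, 240 * 0.125, tolerance = 0.1 * 30)
  # leftward cycles flip the sign convention
  fl <- fit_trajectory(make_pm(P), "left", cfg)
  expect_equal(fl$length, -f$length)
  # a stationary ridge has zero length
  P0 <- sapply(tt, function(t) { d <- dnorm(rel, 0, 4); d / sum(d) })
  f0 <- fit_trajectory(make_pm(P0), "right", cfg)
  expect_lt(abs(f0$length), 2)
  # single decoded column: degenerate
  P1 <- matrix(NA_real_, 18, 10); P1[, 3] <- 1 / 18
  expect_null(fit_trajectory(make_pm(P1), "right", cfg))
})

test_that("posterior averaging requires more than five cycles and preserves identical cycles", {
  cfg <- decoding_config()
  rel <- (seq_len(18) - 9.5) * 4
  tt <- (seq(0, 270, 30) + 45) / 360 * 0.125 - 0.125 / 2
  P <- sapply(tt, function(t) { d <- dnorm(rel, 200 * t, 5); d / sum(d) })
  pm <- make_pm(P)
  mk_dec <- function(n, v) tibble::tibble(
    cycle = seq_len(n), t_mid = seq_len(n), x0 = 120, v_mid = v,
    direction = "right", ok = TRUE, slope = 200, length = 25,
    n_bins = 10, pm = replicate(n, pm, simplify = FALSE))
  # five cycles in the bin: no output ("more than five")
  out5 <- average_posteriors_by_speed(mk_dec(5, 45), cfg)
  expect_true(all(is.na(out5$length[out5$n_cycles == 5])))
  out9 <- average_posteriors_by_speed(mk_dec(9, 45), cfg)
  got <- out9[out9$n_cycles == 9, ]
  single <- fit_trajectory(pm, "right", cfg)
  expect_equal(got$length[1], single$length, tolerance = 1e-6)
})

test_that("a zero-extent sweep decodes to roughly the within-cycle path length", {
  sess <- schematic_session(60, sweep_params("spatial", d_theta = 0),
                            track = track_config(length = 160,
                                                 n_runs_per_direction = 6),
                            n_cells = 60, seed = 19)
  an <- analyze_session(sess, decode = TRUE, optimize_offset = FALSE)
  tr <- an$trajectories
  tr <- tr[tr$ok & tr$x0 > 35 & tr$x0 < 125, ]
  # Eq. 11 limit: mean L ~ v T = 7.5 cm; the band fit attenuates short
  # trajectories, so assert the qualitative limit
  expect_gt(mean(tr$length, na.rm = TRUE), 0.4 * 60 * 0.125)
  expect_lt(mean(tr$length, na.rm = TRUE), 1.6 * 60 * 0.125)
})

test_that("posterior columns sharpen as the population doubles", {
  ent <- vapply(c(10, 20, 40), function(nc) {
    sess <- schematic_session(50, sweep_params("spatial", d_theta = 30),
                              track = track_config(length = 160,
                                                   n_runs_per_direction = 2),
                              n_cells = nc, seed = 20)
    an <- analyze_session(sess, decode = FALSE, optimize_offset = FALSE)
    spk <- an$spikes[an$spikes$significant & !is.na(an$spikes$run_id),
                     c("cell", "t")]
    maps <- thetasweeps:::direction_rate_maps(
      an$spikes, an$behavior, 160, 40, cells = seq_len(nc))
    dec <- decode_session_cycles(spk, an$cycles, an$behavior, maps$rates,
                                 maps$bin_centers, decoding_config())
    cols <- unlist(lapply(dec$pm, function(pm) {
      apply(pm$P, 2, function(p) {
        if (all(!is.finite(p))) return(NA_real_)
        p <- p[p > 0]
        -sum(p * log(p))
      })
    }))
    mean(cols, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(ent) < 0))
})
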