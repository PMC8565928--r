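test_that("characteristic profile is a smooth inverted U with the requested peak", {
  tr <- track_config(length = 240)
  sym <- make_characteristic_profile(tr, peak_speed = 60, asymmetry = 0)
  r <- sym[sym$direction == "right", ]
  expect_equal(r$vbar, rev(r$vbar), tolerance = 1e-10)

  for (asym in c(0, 0.2, 0.5)) {
    p <- make_characteristic_profile(tr, peak_speed = 60, asymmetry = asym)
    for (d in c("right", "left")) {
      v <- p$vbar[p$direction == d]
      mid <- v[length(v) %/% 2]
      expect_lt(v[1], mid)
      expect_lt(v[length(v)], mid)
      # smoothness: no bin-to-bin jump above 20% of peak
      expect_lt(max(abs(diff(v))), 0.2 * 60)
    }
  }

  p60 <- make_characteristic_profile(tr, peak_speed = 60, asymmetry = 0.25)
  expect_equal(max(p60$vbar), 60, tolerance = 1)
  # leftward profile mirrors the rightward one
  expect_equal(p60$vbar[p60$direction == "left"],
               rev(p60$vbar[p60$direction == "right"]))
  expect_error(make_characteristic_profile(tr, peak_speed = -5),
               "positive")
})

test_that("trajectories run corner to corner on the speed profile", {
  tr <- track_config(length = 120, n_runs_per_direction = 4)
  prof <- make_characteristic_profile(tr, peak_speed = 50)
  traj <- generate_trajectory(tr, prof, run_speed_cv = 0, seed = 1)

  runs <- split(traj[!is.na(traj$run_id), ], traj$run_id[!is.na(traj$run_id)])
  expect_length(runs, 8)
  for (r in runs) {
    # corner-to-corner contract
    expect_lt(min(abs(r$x[1] - c(0, 120))), 6)
    expect_lt(min(abs(r$x[nrow(r)] - c(0, 120))), 1e-6)
    expect_gt(abs(r$x[nrow(r)] - r$x[1]), 110)
    # strictly monotone within a run
    expect_true(all(diff(r$x) > 0) || all(diff(r$x) < 0))
  }
  # with zero run-to-run variability the speed equals the profile
  mid <- traj[!is.na(traj$run_id) & traj$x > 20 & traj$x < 100 &
                traj$direction == "right", ]
  v_expect <- profile_speed_at(prof, mid$x, "right")
  v_emp <- abs(diff(traj$x) * tr$tracking_fs)[
    which(!is.na(traj$run_id) & traj$x > 20 & traj$x < 100 &
            traj$direction == "right")]
  expect_equal(v_emp, v_expect, tolerance = 0.05)
})

test_that("per-bin mean speed over many runs matches the profile", {
  tr <- track_config(length = 120, n_runs_per_direction = 25)
  prof <- make_characteristic_profile(tr, peak_speed = 50)
  traj <- generate_trajectory(tr, prof, run_speed_cv = 0.15, seed = 2)
  beh <- annotate_behavior(traj[, c("t", "x")], 120, tr$tracking_fs)
  keep <- !is.na(beh$run_id) & beh$direction == "right" &
    beh$x > 15 & beh$x < 105
  bins <- floor(beh$x[keep] / 4)
  vbar_emp <- tapply(abs(beh$v[keep]), bins, mean)
  vbar_true <- profile_speed_at(prof, as.numeric(names(vbar_emp)) * 4 + 2,
                                "right")
  expect_lt(mean(abs(vbar_emp - vbar_true) / vbar_true), 0.05)
  expect_lt(max(abs(vbar_emp - vbar_true) / vbar_true), 0.12)
})

test_that("theta series is regular at zero jitter and calibrated in frequency", {
  th <- generate_theta_phase(10, mean_freq = 8, cycle_jitter_cv = 0)
  expect_equal(th$cycles$period, rep(0.125, nrow(th$cycles)),
               tolerance = 1e-9)
  # phase is continuous modulo 360 across samples
  dphase <- diff(th$samples$phase) %% 360
  expect_lt(max(abs(dphase - median(dphase))), 1)

  thj <- generate_theta_phase(130, mean_freq = 8, cycle_jitter_cv = 0.1,
                              seed = 3)
  f <- 1 / thj$cycles$period
  expect_gt(length(f), 1000)
  sem <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 8), 2 * sem + 1e-6)
})

test_that("represented position follows each scheme's closed form", {
  sp <- sweep_params("spatial", d_theta = 30)
  bh <- sweep_params("behavior", tau_theta = 0.57)
  # theta0 anchor: at 180 degrees r = x for every scheme
  expect_equal(represented_position(100, 180, sp, 240), 100)
  expect_equal(represented_position(100, 180, bh, 240, vbar = 60), 100)
  # spatial: d_theta = 30, phase 360 -> half a sweep ahead
  expect_equal(represented_position(100, 360 - 1e-9, sp, 240), 115,
               tolerance = 1e-6)
  # behavior: vbar 60, tau 0.57, phase 90 -> 60*0.57*(-90)/360 = -8.55
  expect_equal(represented_position(100, 90, bh, 240, vbar = 60),
               100 - 8.55, tolerance = 1e-9)
  # leftward heading mirrors the sweep
  expect_equal(represented_position(100, 360 - 1e-9, sp, 240,
                                    heading = -1), 85, tolerance = 1e-6)
  expect_error(represented_position(100, 90, bh, 240), "behavior")
})

test_that("the three schemes agree on constant-speed segments (d_theta = v tau)", {
  v <- 50; tau <- 0.5
  traj <- tibble::tibble(t = seq(0, 10, by = 0.025), x = v * seq(0, 10, by = 0.025))
  t <- seq(2, 8, by = 0.01)
  x <- v * t
  ph <- (t * 8 * 360) %% 360
  r_sp <- represented_position(x, ph, sweep_params("spatial", d_theta = v * tau),
                               500, heading = 1)
  r_tm <- represented_position(x, ph, sweep_params("temporal", tau_theta = tau),
                               500, trajectory = traj, t = t)
  r_bh <- represented_position(x, ph, sweep_params("behavior", tau_theta = tau),
                               500, vbar = rep(v, length(x)), heading = 1)
  expect_equal(r_sp, r_tm, tolerance = 1e-6)
  expect_equal(r_sp, r_bh, tolerance = 1e-9)
})

test_that("spike probability reproduces the generative formula", {
  sp <- spiking_params()
  # far from the field center the probability vanishes
  expect_equal(spike_probability(100, 7, 500, 50, 180, sp), 0,
               tolerance = 1e-12)
  # v = 50, theta = 180, r at center: (15 + 10) * 1.35 * 0.002
  expect_equal(spike_probability(100, 7, 100, 50, 180, sp), 0.0675)
  # v = 0, theta = 0: 15 * 0.65 * 0.002
  expect_equal(spike_probability(100, 7, 100, 0, 0, sp), 0.0195)
  expect_error(spike_probability(100, 7, 100, -5, 0, sp), "non-negative")
})

test_that("sessions place cells uniformly, are reproducible, and spike at the Poisson rate", {
  tr <- track_config(length = 240, n_runs_per_direction = 2)
  s1 <- generate_session(tr, sweep_params("spatial", d_theta = 30),
                         n_cells = 20, seed = 7)
  expect_equal(s1$truth$centers, seq(6, 234, by = 12))
  s2 <- generate_session(tr, sweep_params("spatial", d_theta = 30),
                         n_cells = 20, seed = 7)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- generate_session(tr, sweep_params("spatial", d_theta = 30),
                         n_cells = 20, seed = 8)
  expect_false(identical(s1$spikes, s3$spikes))

  # Poisson mean oracle: empirical count within 3 sqrt(sum P) of sum P,
  # with the per-bin probabilities recomputed from the ground truth
  sess <- s1
  sp <- sess$truth$spiking
  tg <- seq(0, max(sess$tracking$t), by = sp$dt)
  xg <- approx(sess$tracking$t, sess$tracking$x, tg, rule = 2)$y
  vtr <- abs(compute_speed(sess$tracking$x, tr$tracking_fs))
  vg <- approx(sess$tracking$t, vtr, tg, rule = 2)$y
  phg <- theta_phase_at(sess$theta, tg)
  hd <- ifelse(xg < dplyr::lead(xg, default = max(xg)), 1, -1)
  for (cell in c(5, 10, 15)) {
    r <- represented_position(xg, phg, sess$truth$params, 240, heading = hd)
    P <- spike_probability(sess$truth$centers[cell],
                           sess$truth$sigma[cell], r, vg, phg, sp)
    n_emp <- sum(sess$spikes$cell == cell)
    expect_lt(abs(n_emp - sum(P)), 3 * sqrt(sum(P)) + 3)
  }
})

test_that("larger sweeps widen the within-cycle span of represented positions", {
  ph <- seq(0, 359, by = 1)
  spans <- vapply(c(10, 20, 40), function(d) {
    r <- represented_position(120, ph, sweep_params("spatial", d_theta = d), 240)
    diff(range(r))
  }, numeric(1))
  expect_true(all(diff(spans) > 0))
})
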