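test_that("cloud normalization is invertible and travel-oriented", {
  spikes <- tibble::tibble(
    cell = 1L, t = c(1, 2, 3), x = c(100, 110, 120),
    phase = c(350, 180, 10), v = c(40, 45, 50),
    direction = "right", run_id = 1L, significant = TRUE)
  cl <- build_cloud(spikes, 1, "right", 100, 120)
  expect_equal(cl$position_norm, c(0, 0.5, 1))
  expect_equal(cl$phase_norm, c(350, 180, 10) / 360)
  # de-normalizing reproduces the raw values
  expect_equal(cl$position_norm * 20 + 100, spikes$x)
  # leftward fields measure position along travel (entry at end)
  spikes_l <- dplyr::mutate(spikes, direction = "left")
  cl_l <- build_cloud(spikes_l, 1, "left", 100, 120)
  expect_equal(cl_l$position_norm, c(1, 0.5, 0))
})

test_that("wrapped ODR fits exact lines with zero error", {
  cl <- line_cloud(-1, 1, wrap = FALSE)
  f <- fit_odr_wrapped(cl)
  expect_equal(f$slope_norm, -1, tolerance = 1e-4)
  expect_equal(f$intercept, 1, tolerance = 1e-4)
  expect_lt(f$error, 1e-4)
  expect_error(fit_odr_wrapped(cl[1, ]), "at least 2")
  same <- tibble::tibble(position_norm = rep(0.5, 5), phase_norm = rep(0.5, 5))
  expect_error(fit_odr_wrapped(same), "identical")
})

test_that("steep wrapped clouds are recovered and match the grid oracle", {
  # a steep precession cloud is a single stripe: the phase range (one
  # full cycle plus boundary overshoot) is crossed over a fraction of
  # the field, and spikes past the cycle boundary appear wrapped
  steep_cloud <- function(slope, n = 80, overshoot = 0.15) {
    span <- (1 + 2 * overshoot) / abs(slope)
    x <- seq(0.5 - span / 2, 0.5 + span / 2, length.out = n)
    tibble::tibble(position_norm = x,
                   phase_norm = (slope * (x - 0.5) + 0.5) %% 1)
  }
  set.seed(15)
  for (slope in c(-2, -3, -5)) {
    f <- fit_odr_wrapped(steep_cloud(slope))
    expect_equal(f$slope_norm, slope, tolerance = abs(slope) * 0.05)
  }
  # exhaustive-grid oracle agrees with the optimizer
  cl <- steep_cloud(-3, n = 50)
  cl$phase_norm <- (cl$phase_norm + rnorm(50, sd = 0.01)) %% 1
  f <- fit_odr_wrapped(cl)
  oracle <- odr_grid_oracle(cl)
  expect_equal(f$slope_norm, oracle$slope, tolerance = 0.05)
  expect_lte(f$objective, oracle$objective + 1e-8)
})

test_that("without wrap-eligible points the fit equals total least squares", {
  set.seed(16)
  x <- runif(120)
  y <- 0.5 - 0.25 * x + rnorm(120, sd = 0.03)
  y <- pmin(pmax(y, 0.31), 0.69)   # keep every point wrap-ineligible
  cl <- tibble::tibble(position_norm = x, phase_norm = y)
  f <- fit_odr_wrapped(cl)
  oracle <- tls_oracle(x, y)
  expect_equal(f$slope_norm, unname(oracle["slope"]), tolerance = 1e-6)
  expect_equal(f$intercept, unname(oracle["intercept"]), tolerance = 1e-6)
})

test_that("shifting already-wrapped points by a full cycle leaves the fit unchanged", {
  set.seed(17)
  cl <- line_cloud(-1.5, 1.25, n = 70, wrap = TRUE)
  cl$phase_norm <- (cl$phase_norm + rnorm(70, sd = 0.02)) %% 1
  f1 <- fit_odr_wrapped(cl)
  shifted <- cl
  hi <- shifted$phase_norm > 0.7
  shifted$phase_norm[hi] <- shifted$phase_norm[hi] - 1
  # the -1-shifted copies are exactly the wrap candidates the objective
  # already considers, so the optimum is identical
  obj1 <- f1$objective
  obj2 <- sum(thetasweeps:::odr_wrapped_dist2(
    c(f1$slope_norm, f1$intercept), shifted$position_norm,
    shifted$phase_norm))
  expect_lte(obj2, obj1 + 1e-8)
})

test_that("physical slopes rescale with the field extent", {
  f <- structure(list(slope_norm = -1, intercept = 1, error = 0, n = 10,
                      objective = 0), class = "precession_fit")
  expect_equal(slope_to_physical(f, 30), -12)
  expect_equal(slope_to_physical(0, 30), 0)
  expect_equal(slope_to_physical(f, 60), -6)
  expect_error(slope_to_physical(f, 0), "positive")
})

test_that("pooled per-speed fits require 12 spikes per bin", {
  set.seed(18)
  cl <- line_cloud(-1, 1, n = 60, wrap = FALSE)
  cl$speed <- c(rep(15, 11), rep(45, 49))   # 11 spikes in the slow bins
  cl$t <- seq_len(60); cl$run_id <- 1L
  ps <- pooled_slopes_by_speed(cl, extent = 30)
  expect_false(any(ps$center %in% c(12, 22)))
  expect_true(all(ps$n_spikes >= 12))
  expect_equal(unique(round(ps$slope_deg_per_cm)), -12)
})

test_that("single passes apply the speed, count, duration, CV and sampling filters", {
  mk_pass <- function(run, n, dur, v, cv) {
    tibble::tibble(
      t = seq(0, dur, length.out = n) + run * 100,
      position_norm = seq(0.05, 0.95, length.out = n),
      phase_norm = 1 - seq(0.05, 0.95, length.out = n),
      speed = v * (1 + cv * sin(seq(0, 6, length.out = n))),
      run_id = run)
  }
  cloud <- dplyr::bind_rows(
    mk_pass(1, 12, 0.8, 40, 0.05),   # valid
    mk_pass(2, 5, 0.8, 40, 0.05),    # too few spikes
    mk_pass(3, 12, 0.2, 40, 0.05),   # too short
    mk_pass(4, 12, 0.8, 40, 0.8),    # speed too variable
    mk_pass(5, 12, 0.8, 1, 0.05))    # too slow
  base_speed <- c(40, 40, 40, 40, 1)
  tracking <- dplyr::bind_rows(lapply(1:5, function(r) {
    tibble::tibble(t = seq(0, 1, by = 0.025) + r * 100,
                   x = seq(100, 130, length.out = 41),
                   v = base_speed[r], run_id = r)
  }))
  tracking$v[tracking$run_id == 4] <-
    40 * (1 + 0.8 * sin(seq(0, 6, length.out = sum(tracking$run_id == 4))))
  sp <- single_pass_slopes(cloud, tracking, 100, 130)
  expect_equal(sp$run_id, 1)
  expect_equal(sp$slope_deg_per_cm, -360 / 30 * (0.9 / 0.9), tolerance = 0.5)
})
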