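test_that("rate maps estimate a homogeneous Poisson rate", {
  set.seed(12)
  fs <- 40
  occ_x <- runif(fs * 600, 0, 240)       # uniform occupancy, 600 s
  spike_x <- runif(5 * 600, 0, 240)      # 5 Hz homogeneous
  rm_ <- compute_rate_map(spike_x, occ_x, fs, 240)
  expect_true(all(abs(rm_$rate - 5) < 3 * sqrt(5 / 10)))
  rm0 <- compute_rate_map(numeric(0), occ_x, fs, 240)
  expect_true(all(rm0$rate == 0))
  expect_error(compute_rate_map(spike_x, numeric(0), fs, 240), "occupancy")
})

test_that("field extent solves the 15% threshold equation for a Gaussian field", {
  # exp(-d^2/(2*7^2)) = 0.15  =>  d = 7 sqrt(2 log(1/0.15)) = 13.65
  rm_ <- gaussian_rate_map(peak_x = 120, sigma = 7, peak_rate = 10)
  f <- detect_fields(rm_, spike_x = rep(120, 30))
  expect_equal(nrow(f), 1)
  d <- 7 * sqrt(2 * log(1 / 0.15))
  expect_equal(f$start, 120 - d, tolerance = 0.15)
  expect_equal(f$end, 120 + d, tolerance = 0.15)
  expect_false(f$incomplete)
  expect_equal(f$size, 2 * d, tolerance = 0.3)
  # the acceptance anchor: sigma = 7 cm fields are 27.3 ~ "27" cm
  expect_equal(f$size, 27.3, tolerance = 0.3)
})

test_that("detection applies the 2 Hz, 25-spike, 66%-edge and screening rules", {
  # sub-threshold peak
  weak <- gaussian_rate_map(peak_rate = 1.5)
  expect_equal(nrow(detect_fields(weak, rep(120, 100))), 0)
  # too few spikes
  strong <- gaussian_rate_map(peak_rate = 10)
  expect_equal(nrow(detect_fields(strong, rep(120, 10))), 0)
  # a field cut by the track end whose rate never drops below 66% of
  # peak cannot be measured and is rejected
  cut <- gaussian_rate_map(peak_x = 238, sigma = 30, peak_rate = 10)
  cut$rate <- pmax(cut$rate, 0)
  expect_equal(nrow(detect_fields(cut, rep(230, 100))), 0)
  # cut on one side only (15% crossing would fall off the track), with
  # the rate below 66% before the end: accepted but incomplete, sized
  # by the doubling rule
  half <- gaussian_rate_map(peak_x = 12, sigma = 7, peak_rate = 10)
  f <- detect_fields(half, rep(20, 100))
  expect_equal(nrow(f), 1)
  expect_true(f$incomplete)
  expect_false(f$start_detected)
  expect_equal(f$size, 2 * (f$end - f$peak_x), tolerance = 1e-9)
  # overlapping-bump screening: secondary peak at 60% with a 40% trough
  twin <- gaussian_rate_map(peak_x = 110, sigma = 7, peak_rate = 10)
  twin$rate <- twin$rate + 6 * exp(-(twin$bin_center - 140)^2 / (2 * 49))
  expect_equal(nrow(detect_fields(twin, rep(115, 100))), 0)
  expect_equal(nrow(detect_fields(twin, rep(115, 100), screen = FALSE)), 1)
})

test_that("field size is scale invariant and doubles one-sided extents", {
  rm1 <- gaussian_rate_map(peak_rate = 10)
  rm2 <- gaussian_rate_map(peak_rate = 40)
  f1 <- detect_fields(rm1, rep(120, 100))
  f2 <- detect_fields(rm2, rep(120, 100))
  expect_equal(f1$size, f2$size, tolerance = 1e-9)
  # doubling rule: one detected end 10 cm from the peak
  fake <- tibble::tibble(peak_x = 50, start = NA, end = 60,
                         start_detected = FALSE, end_detected = TRUE)
  expect_equal(field_size(fake), 20)
})

test_that("sampling index equals brute-force pairwise distance sums", {
  expect_equal(sampling_index(rep(1, 6)), 1)
  expect_equal(sampling_index(rep(0, 6)), 0)
  # 4-bin field: valid {first, last} -> 3/10; valid {first three} -> 4/10
  expect_equal(sampling_index(c(1, 0, 0, 1)), 0.3)
  expect_equal(sampling_index(c(1, 1, 1, 0)), 0.4)
  # brute-force oracle on random patterns
  set.seed(13)
  for (i in 1:20) {
    occ <- runif(10, 0, 0.6)
    valid <- which(occ > 0.3)
    brute <- if (length(valid) < 2) 0 else {
      num <- 0; for (a in valid) for (b in valid) if (b > a) num <- num + (b - a)
      den <- 0; for (a in 1:10) for (b in 1:10) if (b > a) den <- den + (b - a)
      num / den
    }
    expect_equal(sampling_index(occ), brute)
  }
})

test_that("skew matches the hand-computed weighted third moment", {
  # 3-bin map with rates (1, 2, 4) at x = (0, 4, 8)
  rm_ <- tibble::tibble(bin_center = c(0, 4, 8), rate = c(1, 2, 4),
                        occupancy = 1)
  f <- c(1, 2, 4); x <- c(0, 4, 8)
  mu1 <- sum(f * x) / sum(f)
  sig <- sqrt(sum(f * (x - mu1)^2) / sum(f))
  expected <- (sum(f * (x - mu1)^3) / sum(f)) / sig^3
  expect_equal(field_skew(rm_, 0, 8), expected)
  # symmetric map -> 0; mirrored map -> negated
  sym <- gaussian_rate_map(peak_x = 120, sigma = 7)
  expect_lt(abs(field_skew(sym, 100, 140)), 1e-10)
  asym <- tibble::tibble(bin_center = x, rate = rev(f), occupancy = 1)
  expect_equal(field_skew(asym, 0, 8), -expected)
})

test_that("Tukey fences remove extreme outliers and nothing else", {
  v <- c(1:10, 1000)
  expect_equal(remove_outliers(v, k = 3), 1:10)
  expect_equal(remove_outliers(rep(5, 8), k = 3), rep(5, 8))
  set.seed(14)
  x <- rnorm(50)
  out <- remove_outliers(x, k = 6)
  expect_true(all(out %in% x))
  expect_equal(out, x[x %in% out])  # order preserved
  expect_equal(remove_outliers(c(1, 2, NA, 3), k = 3), c(1, 2, 3))
})

test_that("insufficiently sampled speed bins yield missing sizes, never zero", {
  sess <- small_behavior_analysis()
  sz <- sess$analysis$sizes_by_speed
  expect_true(all(is.na(sz$size) | sz$size > 0))
  expect_true(any(is.na(sz$size)))
  expect_true(all(is.na(sz$size[!is.na(sz$sampling_index) &
                                  sz$sampling_index < 0.4])))
})
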