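make_rec <- function(data, fs = 10) {
  nirgait:::new_hemodynamic_recording(data, fs, "HbO")
}

test_that("baseline removal subtracts the first sample and is idempotent", {
  r <- make_rec(rbind(c(5, 5, 5), c(1, 2, 3)))
  out <- remove_baseline(r)
  expect_equal(unname(out$data), rbind(c(0, 0, 0), c(0, 1, 2)))
  set.seed(1)
  r2 <- make_rec(matrix(rnorm(40), 4))
  once <- remove_baseline(r2)
  expect_true(all(once$data[, 1] == 0))
  expect_equal(remove_baseline(once), once)
})

test_that("default band table matches the five physiological ranges", {
  b <- fnirs_bands()
  expect_equal(b$name, c("heart", "respiration", "myogenic",
                         "neurological", "endothelial"))
  expect_equal(b$low,  c(0.6, 0.145, 0.052, 0.021, 0.0095))
  expect_equal(b$high, c(2.0, 0.6, 0.145, 0.052, 0.021))
})

test_that("band decomposition is zero-input, linear, and Nyquist-guarded", {
  z <- make_rec(matrix(0, 2, 100))
  dec <- bandpass_decompose(z)
  expect_length(dec, 5)
  for (d in dec) expect_equal(d$data, z$data)
  set.seed(2)
  x <- make_rec(matrix(rnorm(400), 2))
  d1 <- bandpass_decompose(x)
  x3 <- x; x3$data <- 3 * x$data
  d3 <- bandpass_decompose(x3)
  expect_equal(d3$heart$data, 3 * d1$heart$data, tolerance = 1e-9)
  lo <- make_rec(matrix(rnorm(100), 1), fs = 3)
  expect_error(bandpass_decompose(lo), "heart")
})

test_that("in-band sinusoids pass and cross-band sinusoids are rejected,
           matching the designed transfer function", {
  fs <- 10
  t <- seq(0, 120, by = 1 / fs)
  x <- make_rec(matrix(sin(2 * pi * 1 * t), 1))
  dec <- bandpass_decompose(x)
  core <- 400:800                     # away from edge transients
  # RMS-based amplitude: at 10 Hz sampling the discrete grid of a 1 Hz sine
  # never hits the continuous peak, so max-of-samples underestimates it
  amp_heart <- sqrt(2 * mean(dec$heart$data[1, core]^2))
  amp_neuro <- sqrt(2 * mean(dec$neurological$data[1, core]^2))
  expect_gte(amp_heart, 0.8)
  expect_lt(amp_neuro, 0.05)
  # forward-backward amplitude equals the squared designed magnitude response
  flt <- nirgait:::cheby_bandpass(0.6, 2.0, fs)
  expect_equal(amp_heart, filter_gain(flt, 1, fs)^2, tolerance = 0.02)
})

test_that("gait low-pass has unit DC gain and follows the Butterworth response", {
  fs <- 100
  tr <- structure(list(sampling_rate = fs,
                       angular_velocity = rep(3, 500),
                       angle = rep(-2, 500)), class = "gait_trace")
  out <- lowpass_gait(tr)
  expect_equal(out$angular_velocity, rep(3, 500), tolerance = 1e-8)
  t <- seq(0, 5, by = 1 / fs)
  tr2 <- structure(list(sampling_rate = fs,
                        angular_velocity = sin(2 * pi * 1 * t),
                        angle = sin(2 * pi * 30 * t)), class = "gait_trace")
  out2 <- lowpass_gait(tr2)
  core <- 100:400
  expect_gt(sqrt(2 * mean(out2$angular_velocity[core]^2)), 0.95)  # 1 Hz passes
  expect_lt(sqrt(2 * mean(out2$angle[core]^2)), 0.10)             # 30 Hz rejected
  expect_error(lowpass_gait(tr, cutoff = 60), "Nyquist")
})

test_that("rectify-smooth matches the direct convolution oracle", {
  tr <- structure(list(sampling_rate = 1,
                       angular_velocity = c(-1, 1, -1),
                       angle = c(0, 0, 0)), class = "gait_trace")
  out <- rectify_smooth(tr, window_s = 1)
  expect_equal(out$angular_velocity, c(1, 1, 1))
  x <- c(0, 3, 0, 3, 0)
  tr2 <- structure(list(sampling_rate = 1, angular_velocity = x, angle = x),
                   class = "gait_trace")
  out2 <- rectify_smooth(tr2, window_s = 3)
  expect_equal(out2$angular_velocity, oracle_moving_average(abs(x), 3))
  set.seed(3)
  y <- rnorm(50)
  tr3 <- structure(list(sampling_rate = 10, angular_velocity = y, angle = y),
                   class = "gait_trace")
  out3 <- rectify_smooth(tr3, window_s = 0.5)
  expect_true(all(out3$angular_velocity >= 0))
  expect_equal(out3$angle, oracle_moving_average(abs(y), 5))
})

test_that("cycle segmentation finds rectified-sinusoid minima and handles
           monotone traces", {
  fs <- 100
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  tr <- structure(list(sampling_rate = fs,
                       angular_velocity = abs(sin(2 * pi * 1 * t)),
                       angle = t), class = "gait_trace")
  starts <- segment_cycles(tr)
  # |sin| at 1 Hz has minima every 0.5 s, pruned to >= 0.4 s spacing; allow
  # edge effects of +-1 cycle around the 10 interior minima
  expect_gte(length(starts), 9)
  expect_lte(length(starts), 11)
  expect_true(all(diff(starts) > 0))
  mono <- structure(list(sampling_rate = fs, angular_velocity = t, angle = t),
                    class = "gait_trace")
  expect_equal(as.numeric(segment_cycles(mono)), 1)
})

test_that("staircase equals per-cycle maxima and ignores within-cycle order", {
  expect_equal(staircase(c(1, 3, 2), 1L), c(3, 3, 3))
  expect_equal(staircase(c(1, 2, 5, 4), c(1L, 3L)), c(2, 2, 5, 5))
  set.seed(4)
  x <- runif(30)
  starts <- c(1L, 11L, 21L)
  expect_equal(staircase(x, starts), oracle_per_cycle_max(x, starts))
  # permuting samples within a cycle leaves the staircase unchanged
  xp <- x
  xp[11:20] <- sample(x[11:20])
  expect_equal(staircase(xp, starts), staircase(x, starts))
  # constant within each cycle
  st <- staircase(x, starts)
  expect_equal(as.numeric(tapply(st, findInterval(seq_along(x), starts), sd)),
               rep(0, 3))
})

test_that("full gait conditioning recovers simulator cycle count at default noise", {
  tr <- small_cohort()[[1]]$trials$speed
  g <- preprocess_gait(tr$gait)
  expect_equal(length(g$cycle_starts), tr$gait$truth$n_cycles)
  expect_true(all(g$staircase_speed > 0))
  expect_true(any(g$partial_mask) && !all(g$partial_mask))
})

test_that("zero-phase filtering leaves a band-limited pulse peak in place", {
  fs <- 10
  t <- seq(0, 120, by = 1 / fs)
  pulse <- exp(-((t - 60)^2) / (2 * 4^2)) * sin(2 * pi * 1 * t)
  r <- make_rec(matrix(pulse, 1))
  out <- bandpass_decompose(r)$heart
  expect_equal(which.max(abs(out$data[1, ])), which.max(abs(pulse)))
})
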