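test_that("latent profile ramps the varied parameter and holds the other", {
  cfg <- small_sim_config()
  sp <- generate_latent_profile(cfg, 1, "speed")
  expect_true(all(diff(sp$speed_intensity) >= 0))
  expect_gt(max(sp$speed_intensity) - min(sp$speed_intensity), 0.5)
  expect_equal(sp$stride_intensity, rep(0.65, length(sp$time)))
  st <- generate_latent_profile(cfg, 1, "stride")
  expect_true(all(diff(st$stride_intensity) >= 0))
  expect_equal(st$speed_intensity, rep(0.65, length(st$time)))
  expect_true(all(sp$speed_intensity > 0 & sp$speed_intensity <= 1))
  expect_error(generate_latent_profile(cfg, 1, "jumping"))
})

test_that("zero jitter gives an exactly linear ramp; profiles are seeded", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 20,
                           jitter_amplitude = 0, seed = 9)
  p <- generate_latent_profile(cfg, 1, "speed")
  expect_equal(p$speed_intensity,
               0.3 + 0.7 * p$time / max(p$time), tolerance = 1e-12)
  cfg2 <- small_sim_config()
  a <- generate_latent_profile(cfg2, 3, "speed")
  b <- generate_latent_profile(cfg2, 3, "speed")
  expect_identical(a, b)
  c3 <- generate_latent_profile(cfg2, 4, "speed")
  expect_false(identical(a$speed_intensity, c3$speed_intensity))
})

test_that("HbT equals HbO plus HbR by construction", {
  tr <- small_cohort()[[1]]$trials$speed
  expect_equal(tr$recording$HbT$data,
               tr$recording$HbO$data + tr$recording$HbR$data, tolerance = 1e-12)
})

test_that("zero coupling removes the informative/uninformative distinction", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 30,
                           coupling_gain = 0, seed = 5)
  lat <- generate_latent_profile(cfg, 1, "speed")
  rec <- synthesize_fnirs(cfg, lat, 1, 0)
  # with no coupling, per-channel signal power is statistically level across
  # informative (1-3) and uninformative (4-6) channels
  pw <- apply(rec$HbO$data, 1, var)
  expect_lt(abs(mean(pw[1:3]) - mean(pw[4:6])) / mean(pw), 0.2)
})

test_that("single-band synthesis concentrates power inside the band (FFT oracle)", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 120,
                           drift_slope = 0, noise_sd = 0, seed = 12)
  lat <- generate_latent_profile(cfg, 1, "speed")
  for (b in c(1, 3, 5)) {
    band <- fnirs_bands()[b, ]
    rec <- synthesize_fnirs(cfg, lat, 1, 0, bands = band)
    x <- rec$HbO$data[1, ]
    n <- length(x)
    P <- Mod(fft(x - mean(x)))[2:(n %/% 2)]^2
    f <- (1:(n %/% 2 - 1)) * cfg$fnirs_rate / n
    centroid <- sum(f * P) / sum(P)
    expect_gt(centroid, band$low)
    expect_lt(centroid, band$high)
  }
})

test_that("coupling leaves a recoverable envelope in informative channels", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 60, seed = 2)
  lat <- generate_latent_profile(cfg, 1, "speed")
  rec <- synthesize_fnirs(cfg, lat, 1, 0)
  band1 <- bandpass_decompose(remove_baseline(rec$HbO))[["heart"]]
  env <- oracle_moving_average(abs(band1$data[1, ]), 21)
  driver <- 0.3 * lat$speed_intensity + 0.7 * lat$stride_intensity
  expect_gt(cor(env, driver), 0.5)
})

test_that("gait bursts track the latent intensity cycle by cycle", {
  cfg <- simulation_config(n_subjects = 1, trial_duration = 30,
                           imu_noise_sd = 0, jitter_amplitude = 0, seed = 3)
  lat <- generate_latent_profile(cfg, 1, "speed")
  g <- synthesize_gait(cfg, lat)
  # ramp latent: per-cycle analytic peaks nondecreasing
  expect_true(all(diff(g$truth$peak_speed) >= -1e-9))
  # constant stride: step peaks constant
  expect_lt(diff(range(g$truth$peak_step)), 1e-9)
  # stored ground-truth maxima equal brute-force per-cycle maxima
  bounds <- c(g$truth$cycle_starts, length(g$angular_velocity) + 1)
  for (k in seq_along(g$truth$cycle_starts)) {
    rng <- bounds[k]:(bounds[k + 1] - 1)
    expect_equal(g$truth$max_speed[k], max(g$angular_velocity[rng]))
  }
  expect_error(synthesize_gait(simulation_config(cycle_duration_range = c(2, 1))))
})

test_that("cohorts are reproducible and carry inter-subject variability", {
  cfg <- small_sim_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  gains <- vapply(a, function(s) s$subject_gain, numeric(1))
  expect_false(any(duplicated(gains)))
  flat <- generate_cohort(simulation_config(n_subjects = 3, trial_duration = 10,
                                            subject_gain_sd = 0, seed = 1))
  expect_equal(vapply(flat, function(s) s$subject_gain, numeric(1)), rep(1, 3))
})

test_that("cohort CSV/JSON layout round-trips", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_subjects = 1, trial_duration = 10, seed = 6)
  cohort <- generate_cohort(cfg)
  man <- write_cohort(cohort, dir, cfg)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_error(write_cohort(cohort, dir, cfg), "not empty")
  back <- read_cohort(dir)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$subject_gain, cohort[[1]]$subject_gain)
  expect_equal(back[[1]]$trials$speed$recording$HbO$data,
               cohort[[1]]$trials$speed$recording$HbO$data, tolerance = 1e-12)
  expect_equal(back[[1]]$trials$speed$gait$truth$max_speed,
               cohort[[1]]$trials$speed$gait$truth$max_speed, tolerance = 1e-12)
})
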