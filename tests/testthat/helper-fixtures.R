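# Shared fixtures, built once per test run and memoized. Small scales keep
# the default suite fast; the heavier cross-validation fixture used by the
# recovery checks lives in helper-recovery.R.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# two-subject, 30 s cohort for structural tests
small_cohort <- function() memo("small_cohort", {
  generate_cohort(small_sim_config())
})

small_sim_config <- function() simulation_config(n_subjects = 2, trial_duration = 30,
                                                 seed = 404)

small_extracted <- function() memo("small_extracted", {
  nirgait:::extract_trial(small_cohort()[[1]]$trials$speed, pipeline_config(seed = 404))
})

# independent brute-force oracles -----------------------------------------

oracle_moving_average <- function(x, w) {
  n <- length(x)
  half_l <- floor((w - 1) / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_l)
    hi <- min(n, i + (w - 1 - half_l))
    out[i] <- mean(x[lo:hi])
  }
  out
}

oracle_rmse_relative <- function(pred, real) {
  acc <- 0
  for (i in seq_along(real)) acc <- acc + ((pred[i] - real[i]) / real[i])^2
  sqrt(acc / length(real)) * 100
}

oracle_r_squared <- function(pred, real) {
  num <- 0; den <- 0; m <- mean(real)
  for (i in seq_along(real)) {
    num <- num + (pred[i] - real[i])^2
    den <- den + (real[i] - m)^2
  }
  1 - num / den
}

oracle_f_score <- function(p, c) {
  if (p + abs(c) == 0) return(0)
  2 * p * abs(c) / (p + abs(c))
}

oracle_per_cycle_max <- function(x, starts) {
  bounds <- c(starts, length(x) + 1)
  out <- numeric(length(x))
  for (k in seq_along(starts)) {
    rng <- bounds[k]:(bounds[k + 1] - 1)
    out[rng] <- max(x[rng])
  }
  out
}

# squared magnitude of a digital filter's frequency response at f (Hz);
# forward-backward application squares the magnitude response
filter_gain <- function(flt, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w)
  num <- sum(flt$b * z^(seq_along(flt$b) - 1))
  den <- sum(flt$a * z^(seq_along(flt$a) - 1))
  Mod(num / den)
}
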