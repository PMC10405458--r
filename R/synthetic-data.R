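#' Configuration for the synthetic fNIRS/gait cohort generator
#'
#' Bundles every knob of the coupled simulator: cohort size, trial length,
#' sampling rates, channel montage, coupling strength between the latent gait
#' intensity and the band-limited hemodynamic oscillators, drift/noise levels,
#' inter-subject variability, and the master seed from which all per-subject
#' random streams are derived.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param trial_duration trial length in seconds.
#' @param fnirs_rate hemoglobin sampling rate in Hz. Must exceed twice the
#'   upper edge of the highest physiological band (4 Hz) so all five bands are
#'   representable.
#' @param imu_rate inertial (knee) sampling rate in Hz.
#' @param n_channels number of measurement channels (>= 2).
#' @param informative_channels integer indices (1-based) of channels whose
#'   oscillator amplitudes are coupled to the latent gait intensity; the
#'   remaining channels carry physiological rhythms of constant amplitude.
#' @param coupling_gain dimensionless amplitude gain applied to the latent
#'   intensity in informative channels. Zero removes all recoverable signal.
#' @param drift_slope linear baseline drift in concentration units per second.
#' @param noise_sd white measurement noise standard deviation (concentration
#'   units) added independently to HbO and HbR.
#' @param subject_gain_sd log-normal standard deviation of per-subject
#'   multiplicative gains; 0 makes all subjects identical in gain.
#' @param cycle_duration_range two-element numeric, min/max gait cycle
#'   duration in seconds; per-cycle durations are drawn uniformly from it.
#' @param jitter_amplitude amplitude of the smooth jitter superimposed on the
#'   latent intensity ramp (0 gives an exactly linear ramp).
#' @param imu_noise_sd white noise on the inertial trace (deg/s and deg).
#' @param seed master integer seed; every random stream in the generator is a
#'   pure function of this seed plus subject id / trial mode labels.
#' @return an object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 2, trial_duration = 30, seed = 1)
#' cohort <- generate_cohort(cfg)
simulation_config <- function(n_subjects = 38,
                              trial_duration = 60,
                              fnirs_rate = 10,
                              imu_rate = 100,
                              n_channels = 6,
                              informative_channels = 1:3,
                              coupling_gain = 1,
                              drift_slope = 0.005,
                              noise_sd = 0.08,
                              subject_gain_sd = 0.2,
                              cycle_duration_range = c(0.9, 1.3),
                              jitter_amplitude = 0.03,
                              imu_noise_sd = 1,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, trial_duration > 0, imu_rate > 0)
  if (n_channels < 2) stop("n_channels must be >= 2", call. = FALSE)
  if (fnirs_rate <= 2 * 2.0)
    stop("fnirs_rate must exceed twice the upper edge of the heart-rate band (2 Hz)",
         call. = FALSE)
  if (length(informative_channels) &&
      (min(informative_channels) < 1 || max(informative_channels) > n_channels))
    stop("informative_channels must lie in 1..n_channels", call. = FALSE)
  if (length(cycle_duration_range) != 2 ||
      cycle_duration_range[1] > cycle_duration_range[2] ||
      cycle_duration_range[1] <= 0)
    stop("cycle_duration_range must be (min, max) with 0 < min <= max", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    trial_duration = trial_duration,
    fnirs_rate = fnirs_rate,
    imu_rate = imu_rate,
    n_channels = as.integer(n_channels),
    informative_channels = as.integer(informative_channels),
    coupling_gain = coupling_gain,
    drift_slope = drift_slope,
    noise_sd = noise_sd,
    subject_gain_sd = subject_gain_sd,
    cycle_duration_range = cycle_duration_range,
    jitter_amplitude = jitter_amplitude,
    imu_noise_sd = imu_noise_sd,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Latent gait-intensity profile for one trial
#'
#' Emulates the study protocol in which a subject ramps one gait parameter
#' (walking speed or stride length) from low to high while holding the other
#' constant. The varied parameter follows a monotone-nondecreasing ramp from
#' 0.3 to 1.0 with smooth seeded jitter; the held parameter stays at 0.65.
#' Both intensities are dimensionless in (0, 1].
#'
#' @param config a [simulation_config()].
#' @param subject_id integer subject identifier (seeds the jitter stream).
#' @param mode `"speed"` (speed ramps, stride constant) or `"stride"`.
#' @return a `latent_gait_profile`: list with `time` (s, on the fNIRS grid),
#'   `speed_intensity`, `stride_intensity`, `mode`.
#' @export
generate_latent_profile <- function(config, subject_id, mode = c("speed", "stride")) {
  mode <- match.arg(mode)
  n <- round(config$trial_duration * config$fnirs_rate)
  t <- (seq_len(n) - 1) / config$fnirs_rate
  ramp <- 0.3 + 0.7 * t / max(t)
  jit <- if (config$jitter_amplitude > 0) {
    with_seed(derive_seed(config$seed, subject_id, mode, "latent"), {
      # a handful of slow sinusoids: smooth, band-limited jitter
      freqs <- runif(6, 0.02, 0.1)
      phases <- runif(6, 0, 2 * pi)
      amps <- abs(rnorm(6, 0, config$jitter_amplitude / 2))
      rowSums(sapply(1:6, function(k) amps[k] * sin(2 * pi * freqs[k] * t + phases[k])))
    })
  } else rep(0, n)
  varied <- pmin(1, pmax(1e-3, cummax(ramp + jit)))
  held <- rep(0.65, n)
  out <- if (mode == "speed") list(speed_intensity = varied, stride_intensity = held)
         else list(speed_intensity = held, stride_intensity = varied)
  structure(c(list(time = t), out, list(mode = mode)), class = "latent_gait_profile")
}

#' The five physiological frequency bands
#'
#' Standard fNIRS decomposition bands: cardiac, respiratory, myogenic,
#' neurogenic, and endothelial (metabolic) activity.
#'
#' @return a data.frame with columns `name`, `low`, `high` (Hz).
#' @export
fnirs_bands <- function() {
  data.frame(
    name = c("heart", "respiration", "myogenic", "neurological", "endothelial"),
    low  = c(0.600, 0.145, 0.052, 0.021, 0.0095),
    high = c(2.000, 0.600, 0.145, 0.052, 0.0210),
    stringsAsFactors = FALSE
  )
}

# Which latent intensity drives each band's oscillator amplitude. Every
# band carries a weighted mix of both gait intensities: stride dominates
# the fast (cardiac/respiratory) bands and speed the slow
# (neurogenic/endothelial) bands, with the myogenic band balanced. The
# cross-loading on the fast bands matters because only oscillations faster
# than the analysis window are resolvable by within-window statistics.
band_driver <- function(band_name, speed, stride) {
  w <- switch(band_name,
              heart = 0.3, respiration = 0.3,
              myogenic = 0.5,
              neurological = 0.7, endothelial = 0.7,
              stop("unknown band: ", band_name))
  w * speed + (1 - w) * stride
}

new_hemodynamic_recording <- function(data, sampling_rate, species, channel_ids = NULL) {
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(data)))
  stopifnot(sampling_rate > 0, all(is.finite(data)))
  rownames(data) <- channel_ids
  structure(list(sampling_rate = sampling_rate, species = species,
                 data = data, channel_ids = channel_ids),
            class = "hemodynamic_recording")
}

#' Synthesize a multichannel hemoglobin recording coupled to a latent profile
#'
#' Each channel is a sum over the five physiological bands of narrowband
#' oscillators (amplitude-modulated sinusoids with slow random phase drift).
#' In informative channels the oscillator amplitude is
#' `base + coupling_gain * intensity`, where the driving intensity is the
#' speed ramp for the slow bands and the stride ramp for the fast bands;
#' elsewhere the amplitude is constant at the mid-ramp level. Linear baseline
#' drift and white noise are added per species, HbR is coupled with opposite
#' sign to HbO, and HbT = HbO + HbR by construction.
#'
#' @param config a [simulation_config()].
#' @param latent a [generate_latent_profile()] result covering the trial.
#' @param subject_gain,subject_offset per-subject multiplicative gain and
#'   additive offset.
#' @param bands band table (subset of [fnirs_bands()]) to include.
#' @param stream_seed optional seed for the oscillator/noise stream; defaults
#'   to one derived from `config$seed`.
#' @return named list of three `hemodynamic_recording` objects
#'   (`HbO`, `HbR`, `HbT`), each channels x samples.
#' @export
synthesize_fnirs <- function(config, latent, subject_gain = 1, subject_offset = 0,
                             bands = fnirs_bands(), stream_seed = NULL) {
  n <- length(latent$time)
  if (abs(latent$time[n] - (config$trial_duration - 1 / config$fnirs_rate)) > 1 / config$fnirs_rate)
    stop("latent profile does not cover the trial duration", call. = FALSE)
  t <- latent$time
  C <- config$n_channels
  if (is.null(stream_seed)) stream_seed <- derive_seed(config$seed, "fnirs", latent$mode)
  amp_base <- 0.3
  with_seed(stream_seed, {
    hbo <- matrix(0, C, n)
    hbr <- matrix(0, C, n)
    for (b in seq_len(nrow(bands))) {
      fc <- sqrt(bands$low[b] * bands$high[b])
      driver <- band_driver(bands$name[b], latent$speed_intensity, latent$stride_intensity)
      for (ch in seq_len(C)) {
        informative <- ch %in% config$informative_channels
        amp_o <- if (informative) amp_base + config$coupling_gain * driver
                 else rep(amp_base + config$coupling_gain * 0.65, n)
        amp_r <- 0.5 * (if (informative) amp_base + config$coupling_gain * (1.05 - driver)
                        else rep(amp_base + config$coupling_gain * 0.4, n))
        for (sp in c("o", "r")) {
          phase <- 2 * pi * fc * t + runif(1, 0, 2 * pi) +
            cumsum(rnorm(n, 0, 0.01))          # slow phase drift
          osc <- sin(phase)
          if (sp == "o") hbo[ch, ] <- hbo[ch, ] + amp_o * osc
          else hbr[ch, ] <- hbr[ch, ] + amp_r * osc
        }
      }
    }
    drift <- config$drift_slope * t
    hbo <- subject_gain * hbo +
      matrix(drift, C, n, byrow = TRUE) + subject_offset +
      matrix(rnorm(C * n, 0, config$noise_sd), C, n)
    hbr <- subject_gain * hbr +
      matrix(-0.4 * drift, C, n, byrow = TRUE) +
      matrix(rnorm(C * n, 0, config$noise_sd), C, n)
    list(
      HbO = new_hemodynamic_recording(hbo, config$fnirs_rate, "HbO"),
      HbR = new_hemodynamic_recording(hbr, config$fnirs_rate, "HbR"),
      HbT = new_hemodynamic_recording(hbo + hbr, config$fnirs_rate, "HbT")
    )
  })
}

# Affine maps from dimensionless intensity to physical knee parameters.
speed_peak_from_intensity  <- function(x) 50 + 250 * x   # deg/s
stride_peak_from_intensity <- function(x) 20 + 50 * x    # deg

#' Synthesize a knee inertial trace as a periodic burst train
#'
#' One burst per gait cycle; cycle periods are drawn uniformly from
#' `cycle_duration_range`. The per-cycle peak angular velocity is an affine
#' function (50 + 250 x, deg/s) of the latent speed intensity at the cycle
#' midpoint, and the per-cycle peak angle an affine function (20 + 50 x, deg)
#' of the stride intensity. Ground truth (cycle boundaries, analytic peaks,
#' and exhaustive per-cycle sample maxima of the clean trace) is stored
#' alongside the noisy trace.
#'
#' @param config a [simulation_config()].
#' @param latent a [generate_latent_profile()] result.
#' @param stream_seed optional seed for cycle durations and sensor noise.
#' @return a `gait_trace`: list with `sampling_rate`, `time`,
#'   `angular_velocity`, `angle`, and a `truth` sublist (`cycle_starts`
#'   sample indices, `cycle_mid_times`, `peak_speed`, `peak_step`,
#'   `max_speed`, `max_step`, `n_cycles`).
#' @export
synthesize_gait <- function(config, latent, stream_seed = NULL) {
  if (config$cycle_duration_range[1] > config$cycle_duration_range[2])
    stop("cycle_duration_range is degenerate (min > max)", call. = FALSE)
  if (is.null(stream_seed)) stream_seed <- derive_seed(config$seed, "gait", latent$mode)
  dur <- config$trial_duration
  fs <- config$imu_rate
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(stream_seed, {
    # draw cycle durations until the trial is covered
    durs <- numeric(0)
    while (sum(durs) < dur)
      durs <- c(durs, runif(1, config$cycle_duration_range[1], config$cycle_duration_range[2]))
    starts_t <- cumsum(c(0, durs))[seq_along(durs)]
    ends_t <- pmin(starts_t + durs, dur)
    keep <- starts_t < dur
    starts_t <- starts_t[keep]; ends_t <- ends_t[keep]; durs <- durs[keep]
    k <- findInterval(t, starts_t)                     # cycle index per sample
    phase <- (t - starts_t[k]) / durs[k]               # in [0, 1)
    mid_t <- starts_t + durs / 2
    sp_mid <- approx(latent$time, latent$speed_intensity, xout = pmin(mid_t, max(latent$time)),
                     rule = 2)$y
    st_mid <- approx(latent$time, latent$stride_intensity, xout = pmin(mid_t, max(latent$time)),
                     rule = 2)$y
    vpk <- speed_peak_from_intensity(sp_mid)
    apk <- stride_peak_from_intensity(st_mid)
    burst <- sin(pi * phase)^2
    v_clean <- vpk[k] * burst
    a_clean <- apk[k] * burst
    cycle_starts <- vapply(starts_t, function(s) which.min(abs(t - s)), integer(1))
    cycle_starts[1] <- 1L
    groups <- findInterval(seq_len(n), cycle_starts)
    max_speed <- as.numeric(tapply(v_clean, groups, max))
    max_step <- as.numeric(tapply(a_clean, groups, max))
    v <- v_clean + rnorm(n, 0, config$imu_noise_sd)
    a <- a_clean + rnorm(n, 0, config$imu_noise_sd)
    structure(list(
      sampling_rate = fs, time = t,
      angular_velocity = v, angle = a,
      truth = list(cycle_starts = cycle_starts, cycle_mid_times = mid_t,
                   peak_speed = vpk, peak_step = apk,
                   max_speed = max_speed, max_step = max_step,
                   n_cycles = length(cycle_starts))
    ), class = "gait_trace")
  })
}

#' Generate a reproducible multi-subject coupled fNIRS/gait cohort
#'
#' Each subject receives a log-normal multiplicative gain (sd
#' `subject_gain_sd`) and a Gaussian additive offset, plus one trial per
#' experiment type: a speed-varied trial (stride held) and a stride-varied
#' trial (speed held). Everything is a pure function of `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param modes experiment types to simulate per subject.
#' @return list of `synthetic_subject` objects, each with `subject_id`,
#'   `subject_gain`, `subject_offset` and `trials` (one per mode, each
#'   holding `latent`, `recording`, `gait`).
#' @export
generate_cohort <- function(config, modes = c("speed", "stride")) {
  lapply(seq_len(config$n_subjects), function(id) {
    gain <- with_seed(derive_seed(config$seed, "gain", id),
                      exp(rnorm(1, 0, config$subject_gain_sd)))
    offset <- with_seed(derive_seed(config$seed, "offset", id), rnorm(1, 0, 0.1))
    trials <- lapply(modes, function(m) {
      latent <- generate_latent_profile(config, id, m)
      rec <- synthesize_fnirs(config, latent, gain, offset,
                              stream_seed = derive_seed(config$seed, id, m, "fnirs"))
      gait <- synthesize_gait(config, latent,
                              stream_seed = derive_seed(config$seed, id, m, "gait"))
      list(mode = m, latent = latent, recording = rec, gait = gait)
    })
    names(trials) <- modes
    structure(list(subject_id = id, subject_gain = gain, subject_offset = offset,
                   trials = trials), class = "synthetic_subject")
  })
}

#' Write a synthetic cohort to a directory of CSV/JSON files
#'
#' Layout: `subject_<id>/<mode>/fnirs_<species>.csv` (time + one column per
#' channel), `gait.csv` (time, angular_velocity, angle), and `truth.json`
#' (latent profile, cycle ground truth, subject gain/offset). A top-level
#' `manifest.json` lists files and echoes the configuration.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @param config the [simulation_config()] used (echoed into the manifest).
#' @param force overwrite an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, config, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (subj in cohort) {
    for (trial in subj$trials) {
      tdir <- file.path(dir, sprintf("subject_%02d", subj$subject_id), trial$mode)
      dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
      for (sp in names(trial$recording)) {
        rec <- trial$recording[[sp]]
        df <- data.frame(time = (seq_len(ncol(rec$data)) - 1) / rec$sampling_rate,
                         t(rec$data))
        names(df) <- c("time", rec$channel_ids)
        f <- file.path(tdir, paste0("fnirs_", tolower(sp), ".csv"))
        write.csv(df, f, row.names = FALSE)
        files <- c(files, f)
      }
      gf <- file.path(tdir, "gait.csv")
      write.csv(data.frame(time = trial$gait$time,
                           angular_velocity = trial$gait$angular_velocity,
                           angle = trial$gait$angle),
                gf, row.names = FALSE)
      tj <- file.path(tdir, "truth.json")
      jsonlite::write_json(list(
        subject_id = subj$subject_id, mode = trial$mode,
        subject_gain = subj$subject_gain, subject_offset = subj$subject_offset,
        latent = trial$latent[c("time", "speed_intensity", "stride_intensity")],
        truth = trial$gait$truth
      ), tj, digits = NA, auto_unbox = TRUE)
      files <- c(files, gf, tj)
    }
  }
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   n_subjects = length(cohort),
                   files = sort(gsub(paste0("^", dir, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return list of `synthetic_subject`-like objects (recordings, gait traces
#'   and truth restored from CSV/JSON).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  lapply(sdirs, function(sd) {
    modes <- sort(list.dirs(sd, recursive = FALSE, full.names = FALSE))
    trials <- lapply(modes, function(m) {
      td <- file.path(sd, m)
      truth <- jsonlite::read_json(file.path(td, "truth.json"), simplifyVector = TRUE)
      fs <- manifest$config$fnirs_rate
      rec <- lapply(c(HbO = "hbo", HbR = "hbr", HbT = "hbt"), function(sp) {
        df <- read.csv(file.path(td, paste0("fnirs_", sp, ".csv")))
        new_hemodynamic_recording(t(as.matrix(df[, -1, drop = FALSE])), fs,
                                  toupper(sp), colnames(df)[-1])
      })
      names(rec) <- c("HbO", "HbR", "HbT")
      g <- read.csv(file.path(td, "gait.csv"))
      gait <- structure(list(sampling_rate = manifest$config$imu_rate,
                             time = g$time, angular_velocity = g$angular_velocity,
                             angle = g$angle, truth = truth$truth),
                        class = "gait_trace")
      list(mode = m, latent = c(truth$latent, list(mode = m)),
           recording = rec, gait = gait)
    })
    names(trials) <- modes
    truth1 <- jsonlite::read_json(file.path(sd, modes[1], "truth.json"),
                                  simplifyVector = TRUE)
    structure(list(subject_id = truth1$subject_id,
                   subject_gain = truth1$subject_gain,
                   subject_offset = truth1$subject_offset,
                   trials = trials), class = "synthetic_subject")
  })
}
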