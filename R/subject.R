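#' Configuration ranges for synthetic subject generation
#'
#' Default ranges follow the printed cuff-reference distributions of the
#' study population the simulator emulates: resting systolic pressure
#' 110-130 mmHg, diastolic 56-79 mmHg, resting heart rate 0.9-1.5 Hz
#' (within the 0.67-3.33 Hz heart-rate band of the front end). The
#' between-trial pressure SD (3.5 mmHg) and cuff repeatability
#' (1.5 mmHg) are plausible resting values for a seated subject and an
#' oscillometric cuff, configurable here.
#'
#' @param sbp_range,dbp_range Baseline pressure ranges, mmHg.
#' @param hr_range Heart-rate range, Hz.
#' @param trial_sd Between-trial SD of the latent true pressures, mmHg.
#' @param cuff_noise_sd SD of the cuff reading around the true value, mmHg.
#' @param noise_snr IPG white-noise SNR, dB.
#' @param min_pulse_pressure Smallest admissible SBP-DBP gap, mmHg.
#' @param hemo A [hemo_params()] object.
#' @return Named list of class `subject_config`.
#' @export
subject_config <- function(sbp_range = c(110, 130), dbp_range = c(56, 79),
                           hr_range = c(0.9, 1.5), trial_sd = 3.5,
                           cuff_noise_sd = 1.5, noise_snr = 20,
                           min_pulse_pressure = 25, hemo = hemo_params()) {
  for (r in list(sbp = sbp_range, dbp = dbp_range, hr = hr_range)) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop("configuration error: each range must be c(min, max) with min < max",
           call. = FALSE)
    }
  }
  if (sbp_range[2] <= dbp_range[1]) {
    stop("configuration error: SBP range upper must exceed DBP range lower",
         call. = FALSE)
  }
  if (hr_range[1] < 0.67 || hr_range[2] > 3.33) {
    stop("configuration error: heart rate range must lie within 0.67-3.33 Hz",
         call. = FALSE)
  }
  structure(list(sbp_range = sbp_range, dbp_range = dbp_range,
                 hr_range = hr_range, trial_sd = trial_sd,
                 cuff_noise_sd = cuff_noise_sd, noise_snr = noise_snr,
                 min_pulse_pressure = min_pulse_pressure, hemo = hemo),
            class = "subject_config")
}

#' Draw a synthetic subject profile
#'
#' Samples baseline systolic/diastolic pressures and heart rate uniformly
#' within the configured ranges (enforcing a minimum pulse pressure) and
#' attaches the hemodynamic constants and noise settings. Deterministic
#' given `seed`.
#'
#' @param seed Non-negative integer seed; also stored in the profile.
#' @param config A [subject_config()].
#' @param subject_id Label; defaults to `"S<seed>"`.
#' @return Object of class `subject_profile`.
#' @examples
#' generate_subject(seed = 0)
#' @export
generate_subject <- function(seed = 0, config = subject_config(),
                             subject_id = paste0("S", seed)) {
  stopifnot(inherits(config, "subject_config"))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop("seed must be a single non-negative integer", call. = FALSE)
  }
  prof <- with_local_seed(seed, {
    sbp <- stats::runif(1, config$sbp_range[1], config$sbp_range[2])
    dbp_hi <- min(config$dbp_range[2], sbp - config$min_pulse_pressure)
    if (dbp_hi <= config$dbp_range[1]) dbp_hi <- config$dbp_range[1] + 1e-6
    dbp <- stats::runif(1, config$dbp_range[1], dbp_hi)
    hr <- stats::runif(1, config$hr_range[1], config$hr_range[2])
    list(subject_id = subject_id,
         baseline_SBP = sbp, baseline_DBP = dbp,
         trial_sd = config$trial_sd, heart_rate = hr,
         hemo = config$hemo, noise_snr = config$noise_snr,
         cuff_noise_sd = config$cuff_noise_sd, seed = as.integer(seed))
  })
  stopifnot(prof$baseline_SBP > prof$baseline_DBP,
            prof$heart_rate >= 0.67, prof$heart_rate <= 3.33)
  structure(prof, class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Synthetic subject %s (seed %d)\n", x$subject_id, x$seed))
  cat(sprintf("  baseline SBP/DBP: %.1f / %.1f mmHg (trial SD %.1f)\n",
              x$baseline_SBP, x$baseline_DBP, x$trial_sd))
  cat(sprintf("  heart rate %.2f Hz, IPG SNR %g dB, cuff SD %.1f mmHg\n",
              x$heart_rate, x$noise_snr, x$cuff_noise_sd))
  invisible(x)
}

#' Emulate the cuff-synchronized acquisition protocol
#'
#' Reproduces the study protocol structure: `n_trials` trials, each pairing
#' one cuff reading (systolic + diastolic) with a continuous IPG segment
#' containing at least `beats_per_trial` clean beats around the cuff
#' operating time. Per trial, latent true pressures are drawn around the
#' subject baseline with SD `trial_sd`; the cuff reading is the truth plus
#' Gaussian error with SD `cuff_noise_sd`. The IPG segment is the pressure
#' pulse train passed through the Bramwell-Hill/Ohm impedance model
#' ([pressure_to_impedance()]) plus measurement noise
#' ([add_measurement_noise()]). Latent truths are kept in the output so
#' that simulation studies can separate cuff error from model error.
#'
#' @param profile A [generate_subject()] profile.
#' @param n_trials Number of trials (default 30).
#' @param beats_per_trial Beats to pair with each cuff reading (default 5).
#' @param fs Sampling rate, Hz.
#' @param extra_beats Margin beats simulated beyond `beats_per_trial` so
#'   segmentation has clean beats on both sides of the cuff time.
#' @param noise If `FALSE`, disable white noise, wander, cuff error,
#'   between-trial variability and period jitter (for oracle tests).
#' @return Object of class `ipg_trials`: list with `profile`, `fs` and
#'   `trials`, a list of per-trial records (`trial_index`, `cuff_SBP`,
#'   `cuff_DBP`, `true_SBP`, `true_DBP`, `cuff_time`, `signal`, `t`,
#'   `beat_peak_t` ground-truth systolic times).
#' @examples
#' prof <- generate_subject(seed = 1)
#' d <- emulate_protocol(prof, n_trials = 2)
#' length(d$trials)
#' @export
emulate_protocol <- function(profile, n_trials = 30, beats_per_trial = 5,
                             fs = 500, extra_beats = 4, noise = TRUE) {
  stopifnot(inherits(profile, "subject_profile"),
            n_trials >= 1, beats_per_trial >= 1)
  trial_sd <- if (noise) profile$trial_sd else 0
  cuff_sd <- if (noise) profile$cuff_noise_sd else 0
  snr <- if (noise) profile$noise_snr else Inf
  wander <- if (noise) 0.5 else 0
  jitter <- if (noise) 0.02 else 0

  trials <- with_local_seed(derive_seed(profile$seed, 1), {
    lapply(seq_len(n_trials), function(i) {
      true_sbp <- profile$baseline_SBP + stats::rnorm(1, 0, trial_sd)
      true_dbp <- profile$baseline_DBP + stats::rnorm(1, 0, trial_sd)
      # keep a physiological gap even in extreme draws
      if (true_sbp - true_dbp < 20) true_dbp <- true_sbp - 20
      cuff_sbp <- true_sbp + stats::rnorm(1, 0, cuff_sd)
      cuff_dbp <- true_dbp + stats::rnorm(1, 0, cuff_sd)

      n_beats <- beats_per_trial + extra_beats
      pulse <- pressure_pulse(n_beats = n_beats, fs = fs,
                              sbp = true_sbp, dbp = true_dbp,
                              heart_rate = profile$heart_rate,
                              jitter_sd = jitter)
      Z <- pressure_to_impedance(pulse$P, profile$hemo)
      sig <- add_measurement_noise(Z, fs = fs, snr_db = snr,
                                   wander_rel = wander)
      list(trial_index = i,
           cuff_SBP = cuff_sbp, cuff_DBP = cuff_dbp,
           true_SBP = true_sbp, true_DBP = true_dbp,
           cuff_time = (length(sig) - 1) / fs / 2,
           signal = sig, t = pulse$t, fs = fs,
           beat_peak_t = (pulse$beat_peak - 1) / fs)
    })
  })
  structure(list(profile = profile, fs = fs,
                 beats_per_trial = beats_per_trial, trials = trials),
            class = "ipg_trials")
}

#' @export
print.ipg_trials <- function(x, ...) {
  cat(sprintf("IPG acquisition emulation: subject %s, %d trials @ %g Hz\n",
              x$profile$subject_id, length(x$trials), x$fs))
  cuffs <- vapply(x$trials, function(tr) c(tr$cuff_SBP, tr$cuff_DBP), numeric(2))
  cat(sprintf("  cuff SBP %.1f-%.1f mmHg, DBP %.1f-%.1f mmHg\n",
              min(cuffs[1, ]), max(cuffs[1, ]), min(cuffs[2, ]), max(cuffs[2, ])))
  invisible(x)
}

#' Write a subject dataset to delimited text files
#'
#' Writes `<id>_waveforms.csv` (trial_index, t, signal),
#' `<id>_references.csv` (trial_index, cuff_SBP, cuff_DBP, cuff_time,
#' true_SBP, true_DBP) and `<id>_profile.json` (profile including seed).
#'
#' @param data An [emulate_protocol()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_subject_dataset <- function(data, dir) {
  stopifnot(inherits(data, "ipg_trials"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  id <- data$profile$subject_id
  wf <- do.call(rbind, lapply(data$trials, function(tr) {
    data.frame(trial_index = tr$trial_index, t = tr$t, signal = tr$signal)
  }))
  refs <- do.call(rbind, lapply(data$trials, function(tr) {
    data.frame(trial_index = tr$trial_index,
               cuff_SBP = tr$cuff_SBP, cuff_DBP = tr$cuff_DBP,
               cuff_time = tr$cuff_time,
               true_SBP = tr$true_SBP, true_DBP = tr$true_DBP)
  }))
  paths <- file.path(dir, paste0(id, c("_waveforms.csv", "_references.csv",
                                       "_profile.json")))
  utils::write.csv(wf, paths[1], row.names = FALSE)
  utils::write.csv(refs, paths[2], row.names = FALSE)
  prof <- unclass(data$profile)
  prof$hemo <- unclass(prof$hemo)
  prof$fs <- data$fs
  prof$beats_per_trial <- data$beats_per_trial
  jsonlite::write_json(prof, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a subject dataset written by [write_subject_dataset()]
#'
#' @param dir Directory holding the files.
#' @param subject_id Subject label used in the file names.
#' @return An `ipg_trials` object (without ground-truth beat times).
#' @export
read_subject_dataset <- function(dir, subject_id) {
  wf <- utils::read.csv(file.path(dir, paste0(subject_id, "_waveforms.csv")))
  refs <- utils::read.csv(file.path(dir, paste0(subject_id, "_references.csv")))
  prof <- jsonlite::read_json(file.path(dir, paste0(subject_id, "_profile.json")),
                              simplifyVector = TRUE)
  fs <- prof$fs
  hemo <- do.call(hemo_params, prof$hemo)
  profile <- structure(list(subject_id = prof$subject_id,
                            baseline_SBP = prof$baseline_SBP,
                            baseline_DBP = prof$baseline_DBP,
                            trial_sd = prof$trial_sd,
                            heart_rate = prof$heart_rate, hemo = hemo,
                            noise_snr = prof$noise_snr,
                            cuff_noise_sd = prof$cuff_noise_sd,
                            seed = as.integer(prof$seed)),
                       class = "subject_profile")
  trials <- lapply(split(wf, wf$trial_index), function(d) {
    i <- d$trial_index[1]
    r <- refs[refs$trial_index == i, ]
    list(trial_index = i, cuff_SBP = r$cuff_SBP, cuff_DBP = r$cuff_DBP,
         true_SBP = r$true_SBP, true_DBP = r$true_DBP,
         cuff_time = r$cuff_time, signal = d$signal, t = d$t, fs = fs,
         beat_peak_t = NULL)
  })
  trials <- trials[order(vapply(trials, `[[`, 0, "trial_index"))]
  structure(list(profile = profile, fs = fs,
                 beats_per_trial = prof$beats_per_trial, trials = trials),
            class = "ipg_trials")
}
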