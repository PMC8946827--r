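#' Beat morphology parameters as a function of blood pressure
#'
#' The simulated carotid pulse is a two-Gaussian template: a systolic peak
#' plus a dicrotic (reflected-wave) bump. Two shape parameters are tied
#' monotonically to the beat's pressures so that pressure is recoverable
#' from waveform morphology even after per-beat amplitude normalization:
#' the systolic peak width grows with systolic pressure (stiffer, earlier
#' wave reflection broadens the systolic complex) and the relative dicrotic
#' amplitude grows with diastolic pressure (higher peripheral resistance
#' sustains the reflected wave). The mappings are linear with physiological
#' clamps; they are a modelling choice, not a measured relation.
#'
#' @param sbp Systolic pressure, mmHg.
#' @param dbp Diastolic pressure, mmHg.
#' @return List with `mu_sys`, `sigma_sys`, `mu_dic`, `sigma_dic`,
#'   `dicrotic_amp` (all in beat-phase units except the dimensionless
#'   amplitude ratio).
#' @export
beat_morphology <- function(sbp, dbp) {
  sigma_sys <- 0.085 * (1 + 0.025 * (sbp - 120))
  sigma_sys <- pmin(pmax(sigma_sys, 0.035), 0.18)
  dicrotic_amp <- 0.45 + 0.018 * (dbp - 70)
  dicrotic_amp <- pmin(pmax(dicrotic_amp, 0.05), 0.90)
  list(mu_sys = 0.18, sigma_sys = sigma_sys,
       mu_dic = 0.48, sigma_dic = 0.07,
       dicrotic_amp = dicrotic_amp)
}

# Raw (unnormalized) template value on beat phase in [0, 1).
beat_template <- function(phase, sbp, dbp) {
  m <- beat_morphology(sbp, dbp)
  exp(-0.5 * ((phase - m$mu_sys) / m$sigma_sys)^2) +
    m$dicrotic_amp * exp(-0.5 * ((phase - m$mu_dic) / m$sigma_dic)^2)
}

#' Generate a sampled arterial pressure pulse train
#'
#' Concatenates `n_beats` template beats at the subject's heart rate with
#' optional period jitter. Within each beat the template is min-max scaled
#' on its own sample grid so that the sampled per-beat maximum equals that
#' beat's systolic pressure and the minimum equals its diastolic pressure.
#'
#' @param profile Optional subject profile (see [generate_subject()]);
#'   supplies defaults for `sbp`, `dbp` and `heart_rate`.
#' @param n_beats Number of beats to generate (>= 1).
#' @param fs Sampling rate, Hz (>= 50).
#' @param seed Optional seed controlling the period jitter draw.
#' @param sbp,dbp Per-beat systolic/diastolic pressures, mmHg; scalars are
#'   recycled across beats.
#' @param heart_rate Mean heart rate, Hz.
#' @param jitter_sd Relative SD of the beat period (0 = strictly periodic).
#' @return List with `t` (s), `P` (mmHg), `beat_onset` and `beat_peak`
#'   (sample indices per beat), `fs`.
#' @examples
#' p <- pressure_pulse(n_beats = 3, fs = 500, sbp = 120, dbp = 70,
#'                     heart_rate = 1.2, jitter_sd = 0)
#' range(p$P)  # c(70, 120)
#' @export
pressure_pulse <- function(profile = NULL, n_beats = 5, fs = 500, seed = NULL,
                           sbp = NULL, dbp = NULL, heart_rate = NULL,
                           jitter_sd = 0.02) {
  if (!is.null(profile)) {
    sbp <- sbp %||% profile$baseline_SBP
    dbp <- dbp %||% profile$baseline_DBP
    heart_rate <- heart_rate %||% profile$heart_rate
  }
  if (is.null(sbp) || is.null(dbp) || is.null(heart_rate)) {
    stop("sbp, dbp and heart_rate are required (directly or via profile)",
         call. = FALSE)
  }
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  if (fs < 50) {
    stop("sampling error: fs = ", fs,
         " Hz is too low to resolve the pulse template (need >= 50 Hz)",
         call. = FALSE)
  }
  sbp <- rep_len(sbp, n_beats)
  dbp <- rep_len(dbp, n_beats)
  if (any(sbp <= dbp)) stop("each beat needs sbp > dbp", call. = FALSE)

  periods <- with_local_seed(seed, {
    1 / heart_rate * (1 + if (jitter_sd > 0) stats::rnorm(n_beats, 0, jitter_sd)
                          else rep(0, n_beats))
  })
  periods <- pmax(periods, 1 / 3.33)  # never faster than the HR band upper edge

  P <- vector("list", n_beats)
  onset <- integer(n_beats)
  peak <- integer(n_beats)
  pos <- 0L
  for (b in seq_len(n_beats)) {
    n_b <- max(round(periods[b] * fs), 16L)
    phase <- (seq_len(n_b) - 1) / n_b
    raw <- beat_template(phase, sbp[b], dbp[b])
    s <- (raw - min(raw)) / (max(raw) - min(raw))
    P[[b]] <- dbp[b] + (sbp[b] - dbp[b]) * s
    onset[b] <- pos + 1L
    peak[b] <- pos + which.max(s)
    pos <- pos + n_b
  }
  P <- unlist(P, use.names = FALSE)
  list(t = (seq_along(P) - 1) / fs, P = P,
       beat_onset = onset, beat_peak = peak, fs = fs)
}

#' Add acquisition noise to an impedance waveform
#'
#' Stands in for the analog acquisition chain: additive white Gaussian
#' noise at a prescribed signal-to-noise ratio plus a slow baseline-wander
#' sinusoid below the 0.3 Hz lower edge of the front-end bandpass (so the
#' digital bandpass removes it). SNR is defined on AC power,
#' `10*log10(var(Z)/var(noise))`.
#'
#' @param Z Clean impedance waveform, ohm.
#' @param fs Sampling rate, Hz.
#' @param snr_db Target SNR in dB; `Inf` disables the white noise.
#' @param seed Optional seed for the noise draw.
#' @param wander_rel Baseline-wander amplitude relative to the waveform's
#'   peak-to-peak range (0 disables wander).
#' @param wander_freq Wander frequency, Hz (must be < 0.3).
#' @return Noisy waveform, same length as `Z`.
#' @export
add_measurement_noise <- function(Z, fs, snr_db = 20, seed = NULL,
                                  wander_rel = 0.5, wander_freq = 0.1) {
  if (!is.finite(wander_freq) || wander_freq <= 0 || wander_freq >= 0.3) {
    stop("wander_freq must lie in (0, 0.3) Hz so the bandpass removes it",
         call. = FALSE)
  }
  if (is.na(snr_db)) stop("snr_db must be a number or Inf", call. = FALSE)
  n <- length(Z)
  with_local_seed(seed, {
    out <- Z
    if (wander_rel > 0) {
      amp <- wander_rel * (max(Z) - min(Z))
      phi <- stats::runif(1, 0, 2 * pi)
      out <- out + amp * sin(2 * pi * wander_freq * (seq_len(n) - 1) / fs + phi)
    }
    if (is.finite(snr_db)) {
      sig_sd <- stats::sd(Z)
      noise_sd <- sig_sd * 10^(-snr_db / 20)
      out <- out + stats::rnorm(n, 0, noise_sd)
    }
    out
  })
}
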