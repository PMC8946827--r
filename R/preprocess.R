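#' Digital emulation of the analog front-end bandpass
#'
#' Fourth-order Butterworth bandpass (default 0.3-5 Hz, covering the
#' 0.67-3.33 Hz heart-rate band with margin for harmonics), applied
#' forward-backward (zero phase) so beat morphology is not skewed before
#' feature extraction. The analog original is causal; zero-phase
#' application is a deliberate offline deviation that preserves peak
#' timing to within a sample.
#'
#' @param x Input waveform.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz.
#' @param order Butterworth prototype order.
#' @return Filtered waveform, same length as `x`; DC is removed.
#' @examples
#' fs <- 100
#' t <- seq(0, 10, by = 1 / fs)
#' x <- sin(2 * pi * 1.2 * t) + 5           # in-band tone + DC
#' y <- bandpass_filter(x, fs)
#' sd(y[200:800]) * sqrt(2)                 # ~ unit amplitude, DC gone
#' @export
bandpass_filter <- function(x, fs, low = 0.3, high = 5, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("configuration error: need 0 < low < high < fs/2 (Nyquist ", fs / 2,
         " Hz)", call. = FALSE)
  }
  sos <- butter_bandpass_sos(order, low, high, fs)
  # odd-reflection padding suppresses the long start-up transient of the
  # 0.3 Hz highpass corner on short records; pad ~3 corner periods
  n <- length(x)
  p <- min(n - 1L, ceiling(3 * fs / low))
  xp <- if (p > 0L) {
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else x
  y <- xp
  for (s in sos) y <- signal::filtfilt(s$b, s$a, y)
  as.numeric(y[(p + 1):(p + n)])
}

# Digital Butterworth bandpass as second-order sections (biquads).
# The order-2*`order` transfer function in direct (b, a) form is severely
# ill-conditioned for corners far below Nyquist (0.3 Hz at fs = 500 Hz), so
# the filter is designed analytically - Butterworth prototype poles,
# lowpass-to-bandpass transform, bilinear transform with prewarping - and
# kept factored as conjugate-pair biquads, each numerically benign.
butter_bandpass_sos <- function(order, low, high, fs) {
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  wl <- warp(low); wh <- warp(high)
  w0sq <- wl * wh
  bw <- wh - wl
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles
  # each prototype pole maps to a pole pair of s^2 - p*bw*s + w0^2 = 0
  pb <- proto * bw
  disc <- sqrt(pb^2 - 4 * w0sq)
  s_poles <- c((pb + disc) / 2, (pb - disc) / 2)
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)       # bilinear

  # pair each pole with its conjugate partner: sort by imaginary part sign
  pos <- z_poles[Im(z_poles) >= 0]
  sos <- lapply(pos, function(zp) {
    list(b = c(1, 0, -1),                                   # zeros at +1, -1
         a = c(1, -2 * Re(zp), Mod(zp)^2))
  })
  # normalize to unit gain at the (digital) center frequency
  f0 <- atan(sqrt(w0sq) / (2 * fs)) * fs / pi
  z0 <- exp(2i * pi * f0 / fs)
  g <- prod(vapply(sos, function(s) {
    Mod(sum(s$b * z0^-(0:2)) / sum(s$a * z0^-(0:2)))
  }, 0))
  gs <- (1 / g)^(1 / length(sos))
  lapply(sos, function(s) { s$b <- s$b * gs; s })
}

#' Analytic magnitude response of the zero-phase bandpass
#'
#' Closed-form Butterworth bandpass magnitude
#' `|H(f)|^2 = 1 / (1 + ((f^2 - f0^2) / (f * BW))^(2 * order))`, squared
#' once more because [bandpass_filter()] applies the filter forward and
#' backward. Band edges are prewarped to match the bilinear-transform
#' discretization at sampling rate `fs`.
#'
#' @inheritParams bandpass_filter
#' @param f Frequencies at which to evaluate, Hz.
#' @return Gain (linear amplitude ratio) at `f`.
#' @export
bandpass_gain <- function(f, fs, low = 0.3, high = 5, order = 4) {
  warp <- function(fr) fs / pi * tan(pi * fr / fs)
  wl <- warp(low); wh <- warp(high); w <- warp(f)
  f0sq <- wl * wh
  bw <- wh - wl
  h2 <- 1 / (1 + ((w^2 - f0sq) / (w * bw))^(2 * order))
  h2  # |H|^2: one forward and one backward pass
}

#' Segment an IPG recording into beats
#'
#' Detects systolic peaks on a bandpassed waveform by greedy
#' highest-first selection of local maxima subject to a minimum inter-peak
#' distance `fs / max_hr` and a prominence threshold relative to the
#' signal's amplitude, then places beat boundaries at the signal minima
#' between consecutive peaks (trough-to-trough beats).
#'
#' The impedance of an artery segment falls when pressure rises, so on raw
#' impedance units systole is a trough; pass the negated waveform (as
#' [extract_beats()] does) so the systolic anchor is a positive peak.
#'
#' @param x Bandpassed waveform.
#' @param fs Sampling rate, Hz.
#' @param min_hr,max_hr Admissible heart-rate band, Hz.
#' @param min_prominence Peak height threshold as a fraction of the
#'   signal's robust amplitude (98th percentile of positive excursion).
#' @return Data frame with one row per beat: `peak`, `start`, `end`
#'   (sample indices) and `t_peak` (s). Zero rows if no peaks are found.
#' @export
segment_beats <- function(x, fs, min_hr = 0.67, max_hr = 3.33,
                          min_prominence = 0.4) {
  n <- length(x)
  empty <- data.frame(peak = integer(0), start = integer(0),
                      end = integer(0), t_peak = numeric(0))
  if (n < 3L) return(empty)
  amp <- stats::quantile(x, 0.98, names = FALSE)
  if (!is.finite(amp) || amp <= 0) return(empty)
  thr <- min_prominence * amp

  is_max <- x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]
  cand <- which(is_max) + 1L
  cand <- cand[x[cand] >= thr]
  if (length(cand) == 0L) return(empty)

  # estimate the beat period from the autocorrelation inside the
  # heart-rate band; the dicrotic bump repeats at the beat period too, so
  # a fixed fs/max_hr spacing would admit it as a second peak at low
  # heart rates
  lag_min <- floor(fs / max_hr)
  lag_max <- min(n - 1L, ceiling(fs / min_hr))
  min_dist <- lag_min
  if (lag_max > lag_min + 2L) {
    ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                     demean = TRUE)$acf[-1]
    period <- lag_min + which.max(ac[lag_min:lag_max]) - 1L
    min_dist <- max(lag_min, floor(0.6 * period))
  }
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (all(abs(p - keep) >= min_dist)) keep <- c(keep, p)
  }
  peaks <- sort(keep)

  max_period <- ceiling(fs / min_hr)
  starts <- integer(length(peaks))
  ends <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    lo <- if (i == 1L) max(1L, peaks[1] - max_period) else peaks[i - 1]
    hi <- if (i == length(peaks)) min(n, peaks[i] + max_period) else peaks[i + 1]
    starts[i] <- lo + which.min(x[lo:peaks[i]]) - 1L
    ends[i] <- peaks[i] + which.min(x[peaks[i]:hi]) - 1L
  }
  data.frame(peak = peaks, start = starts, end = ends,
             t_peak = (peaks - 1) / fs)
}

#' Select the beats paired with a cuff reading
#'
#' The acquisition protocol records the cuff reading once per trial; the
#' `k` beats whose systolic anchors are nearest to the cuff operating time
#' (ties resolved toward the earlier beat) are paired with it, preserving
#' time order. This operationalizes selecting waveforms "around" the cuff
#' measurement window.
#'
#' @param beats Data frame from [segment_beats()].
#' @param cuff_time Cuff operating time, s.
#' @param k Number of beats to select.
#' @return `beats` subset with `k` rows, time-ordered.
#' @export
select_trial_beats <- function(beats, cuff_time, k = 5) {
  if (nrow(beats) < k) {
    stop("insufficient beats: trial has ", nrow(beats),
         " segmentable beats but ", k, " are required", call. = FALSE)
  }
  d <- abs(beats$t_peak - cuff_time)
  ord <- order(d, beats$t_peak)  # ties -> earlier beat
  sel <- sort(ord[seq_len(k)])
  beats[sel, , drop = FALSE]
}

#' Resample and normalize one beat to the model's fixed-length form
#'
#' Linear-interpolation resampling to `target_len` samples followed by
#' per-beat min-max scaling to \[0, 1\]. Per-beat amplitude scaling removes
#' the unknown ohm-scale gain of the acquisition chain, so downstream
#' features carry morphology only. A constant beat maps to the zero
#' vector by convention.
#'
#' @param beat Numeric vector of beat samples.
#' @param target_len Output length.
#' @return Numeric vector of length `target_len` in \[0, 1\].
#' @export
normalize_beat <- function(beat, target_len = 128) {
  if (length(beat) == 0L) stop("beat must be non-empty", call. = FALSE)
  y <- if (length(beat) == 1L) {
    rep(beat, target_len)
  } else {
    stats::approx(seq_along(beat), beat,
                  xout = seq(1, length(beat), length.out = target_len))$y
  }
  rng <- range(y)
  if (rng[2] - rng[1] <= 0) return(rep(0, target_len))
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Run the full pre-processing chain on an emulated acquisition
#'
#' For every trial: negate the raw impedance signal (so systole is a
#' positive peak), bandpass, segment beats, select the `beats_per_trial`
#' beats nearest the cuff time and resample/normalize each to
#' `target_len`. Returns the beat matrix together with its cuff labels.
#'
#' @param data An [emulate_protocol()] (or [read_subject_dataset()]) result.
#' @param target_len Samples per normalized beat.
#' @param low,high,order Bandpass settings, see [bandpass_filter()].
#' @return List of class `ipg_beats`: `beats` (matrix, one row per beat),
#'   `meta` (data frame: subject_id, trial_index, beat_index, t_peak,
#'   cuff_SBP, cuff_DBP, true_SBP, true_DBP).
#' @export
extract_beats <- function(data, target_len = 128, low = 0.3, high = 5,
                          order = 4) {
  stopifnot(inherits(data, "ipg_trials"))
  k <- data$beats_per_trial
  rows <- list()
  mats <- list()
  for (tr in data$trials) {
    filt <- bandpass_filter(-tr$signal, data$fs, low = low, high = high,
                            order = order)
    beats <- segment_beats(filt, data$fs)
    sel <- tryCatch(select_trial_beats(beats, tr$cuff_time, k = k),
                    error = function(e) {
                      stop("trial ", tr$trial_index, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    for (j in seq_len(nrow(sel))) {
      seg <- filt[sel$start[j]:sel$end[j]]
      mats[[length(mats) + 1L]] <- normalize_beat(seg, target_len)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = data$profile$subject_id, trial_index = tr$trial_index,
        beat_index = j, t_peak = sel$t_peak[j],
        cuff_SBP = tr$cuff_SBP, cuff_DBP = tr$cuff_DBP,
        true_SBP = tr$true_SBP %||% NA_real_,
        true_DBP = tr$true_DBP %||% NA_real_)
    }
  }
  structure(list(beats = do.call(rbind, mats), meta = do.call(rbind, rows),
                 target_len = target_len, fs = data$fs),
            class = "ipg_beats")
}

#' @export
print.ipg_beats <- function(x, ...) {
  cat(sprintf("Normalized IPG beats: %d beats x %d samples from %d trials\n",
              nrow(x$beats), ncol(x$beats), length(unique(x$meta$trial_index))))
  invisible(x)
}

#' Write and read an extracted beat set
#'
#' The beat metadata goes to `beats_meta.csv`; the resampled beat matrix
#' goes to `beats.rds` (an R binary array container; no HDF5 binding is
#' required at run time).
#'
#' @param beats An [extract_beats()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_beats <- function(beats, dir) {
  stopifnot(inherits(beats, "ipg_beats"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  paths <- file.path(dir, c("beats_meta.csv", "beats.rds"))
  utils::write.csv(beats$meta, paths[1], row.names = FALSE)
  saveRDS(list(beats = beats$beats, target_len = beats$target_len,
               fs = beats$fs), paths[2])
  invisible(paths)
}

#' @rdname write_beats
#' @export
read_beats <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "beats_meta.csv"))
  arr <- readRDS(file.path(dir, "beats.rds"))
  structure(list(beats = arr$beats, meta = meta,
                 target_len = arr$target_len, fs = arr$fs),
            class = "ipg_beats")
}
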