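test_that("bandpass removes DC and preserves length", {
  fs <- 500
  x <- rep(5, 60 * fs)
  y <- bandpass_filter(x, fs = fs)
  expect_length(y, length(x))
  # the 0.3 Hz highpass transient needs several corner periods to die out
  expect_lt(max(abs(y[(15 * fs):(45 * fs)])), 1e-6 * 5)
})

test_that("bandpass matches the analytic Butterworth magnitude response", {
  fs <- 500
  t <- seq(0, 40, by = 1 / fs)
  mid <- seq(10 * fs, 30 * fs)
  for (f in c(0.8, 1.2, 2, 3.3)) {  # heart-rate band
    y <- bandpass_filter(sin(2 * pi * f * t), fs)
    amp <- sqrt(2) * stats::sd(y[mid])
    expect_equal(amp, bandpass_gain(f, fs), tolerance = 0.01)
  }
  # out-of-band power-line frequency: at least 40 dB down
  y50 <- bandpass_filter(sin(2 * pi * 50 * t), fs)
  expect_lt(sqrt(2) * stats::sd(y50[mid]), 10^(-40 / 20))
})

test_that("bandpass is zero-phase on an in-band tone", {
  fs <- 250
  t <- seq(0, 30, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t)
  y <- bandpass_filter(x, fs)
  xp <- which(diff(sign(diff(x))) < 0) + 1L
  yp <- which(diff(sign(diff(y))) < 0) + 1L
  xp <- xp[xp > 5 * fs & xp < 25 * fs]
  for (p in xp) expect_lte(min(abs(yp - p)), 1)
})

test_that("bandpass validates its corner frequencies", {
  expect_error(bandpass_filter(rnorm(100), fs = 8, low = 0.3, high = 5),
               "configuration error")
  expect_error(bandpass_filter(rnorm(100), fs = 100, low = 5, high = 0.3),
               "configuration error")
})

test_that("segmentation finds each beat of a clean pulse train", {
  p <- pressure_pulse(n_beats = 5, fs = 500, sbp = 120, dbp = 70,
                      heart_rate = 1.2, jitter_sd = 0)
  Z <- pressure_to_impedance(p$P, hemo_params())
  filt <- bandpass_filter(-Z, 500)
  beats <- segment_beats(filt, 500)
  expect_equal(nrow(beats), 5)
  expect_true(all(diff(beats$peak) > 0))
  expect_true(all(beats$start <= beats$peak & beats$peak <= beats$end))
})

test_that("segmentation returns an empty table on flat input", {
  expect_equal(nrow(segment_beats(rep(0, 1000), 500)), 0)
  expect_equal(nrow(segment_beats(numeric(0), 500)), 0)
})

test_that("detected anchors match the simulator's beat times", {
  prof <- generate_subject(seed = 9)
  d <- emulate_protocol(prof, n_trials = 3, extra_beats = 25, noise = FALSE)
  for (tr in d$trials) {
    filt <- bandpass_filter(-tr$signal, d$fs)
    beats <- segment_beats(filt, d$fs)
    expect_equal(nrow(beats), length(tr$beat_peak_t))
    expect_lte(max(abs(beats$t_peak - tr$beat_peak_t)) * d$fs, 2)
  }
})

test_that("segmentation recall and precision are 1 on noise-free subjects", {
  miss <- 0L
  extra <- 0L
  for (s in 1:100) {
    prof <- generate_subject(seed = 1000 + s)
    d <- emulate_protocol(prof, n_trials = 1, noise = FALSE)
    tr <- d$trials[[1]]
    beats <- segment_beats(bandpass_filter(-tr$signal, d$fs), d$fs)
    truth <- tr$beat_peak_t
    matched <- vapply(truth, function(tt) any(abs(beats$t_peak - tt) < 0.1),
                      TRUE)
    miss <- miss + sum(!matched)
    extra <- extra + (nrow(beats) - sum(matched))
  }
  expect_identical(miss, 0L)   # recall = 1
  expect_identical(extra, 0L)  # precision = 1
})

test_that("beat selection picks the k anchors nearest the cuff time", {
  mk <- function(tp) data.frame(peak = round(tp * 500), start = 1, end = 2,
                                t_peak = tp)
  # symmetric case: middle five of ten
  b <- mk(1:10)
  sel <- select_trial_beats(b, cuff_time = 5.5, k = 5)
  expect_equal(sel$t_peak, 3:7)
  # exactly five available
  expect_equal(select_trial_beats(mk(1:5), cuff_time = 100, k = 5)$t_peak, 1:5)
  # brute-force nearest-k oracle
  b7 <- mk(1:7)
  d <- abs(b7$t_peak - 2.2)
  oracle <- sort(b7$t_peak[order(d, b7$t_peak)][1:5])
  sel <- select_trial_beats(b7, cuff_time = 2.2, k = 5)
  expect_equal(sel$t_peak, oracle)
  expect_equal(sel$t_peak, 1:5)
  expect_error(select_trial_beats(mk(1:3), cuff_time = 2, k = 5),
               "insufficient beats")
})

test_that("beat selection resolves ties toward the earlier beat", {
  b <- data.frame(peak = 1:4, start = 1:4, end = 1:4, t_peak = c(1, 2, 4, 5))
  sel <- select_trial_beats(b, cuff_time = 3, k = 3)
  # distances: 2, 1, 1, 2 -> beats at 2 and 4 first, then tie 1 vs 5 -> 1
  expect_equal(sel$t_peak, c(1, 2, 4))
})

test_that("beat normalization resamples and scales into [0, 1]", {
  x <- seq(0, 1, length.out = 128)
  expect_equal(normalize_beat(x, 128), x)
  expect_equal(normalize_beat(rep(3, 50), 128), rep(0, 128))
  ramp <- normalize_beat(seq(2, 9, length.out = 100), 200)
  expect_length(ramp, 200)
  expect_true(all(diff(ramp) >= -1e-12))
  expect_equal(range(ramp), c(0, 1))
  expect_error(normalize_beat(numeric(0)), "non-empty")
})

test_that("the preprocessing chain yields beats_per_trial beats per trial", {
  fx <- default_subject_pipeline()
  meta <- fx$beats$meta
  expect_equal(nrow(fx$beats$beats), 150)
  expect_equal(as.integer(table(meta$trial_index)), rep(5L, 30))
  expect_true(all(fx$beats$beats >= 0 & fx$beats$beats <= 1))
  # beats within each trial are time-ordered
  for (i in unique(meta$trial_index)) {
    expect_true(all(diff(meta$t_peak[meta$trial_index == i]) > 0))
  }
})
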