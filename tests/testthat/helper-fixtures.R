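# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# The default synthetic subject taken end to end through preprocessing and
# feature extraction (the acquisition-protocol study conditions: 30 trials,
# 5 beats per trial, 20 dB SNR, 1.5 mmHg cuff noise).
default_subject_pipeline <- function() {
  if (!is.null(.fixture_env$dsp)) return(.fixture_env$dsp)
  prof <- generate_subject(seed = 0)
  dat <- emulate_protocol(prof)
  beats <- extract_beats(dat)
  images <- beats_to_images(beats)
  split <- split_dataset(beats$meta$trial_index, seed = 0)
  .fixture_env$dsp <- list(prof = prof, dat = dat, beats = beats,
                           images = images, split = split)
  .fixture_env$dsp
}

# Small network for fast training tests.
tiny_net_config <- function(...) {
  ssrnet_config(input_shape = c(16, 16), widths = 4, head_channels = 3, ...)
}

# Independent type-7 (linear interpolation, median-inclusive) quantile,
# written from the sorted-order definition.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force scan of the convergence definition: the epoch of the last
# improvement of the running-best loss by at least rel_tol (relative),
# declared only if at least `patience` epochs were observed after it.
oracle_convergence <- function(hist, rel_tol = 0.02, patience = 10) {
  n <- length(hist)
  if (n < patience + 1) stop("history too short")
  e <- 1L
  for (j in 2:n) {
    best <- min(hist[seq_len(j - 1)])
    if ((best - hist[j]) / best >= rel_tol) e <- j
  }
  if (n - e >= patience) e else NA_integer_
}
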