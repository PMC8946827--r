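test_that("impedance model reproduces the reference state and Ohm's law", {
  h <- hemo_params()
  expect_equal(pressure_to_impedance(h$P0, h), h$L / (h$sigma * h$A0))
  # direct substitution: L = 0.02 m, sigma = 0.6 S/m, A = 3e-5 m^2
  h2 <- hemo_params(L = 0.02, sigma = 0.6, A0 = 3e-5)
  expect_equal(pressure_to_impedance(h2$P0, h2), 0.02 / (0.6 * 3e-5),
               tolerance = 1e-12)
  expect_equal(pressure_to_impedance(h2$P0, h2), 1111.111, tolerance = 1e-4)
})

test_that("impedance is strictly decreasing in pressure", {
  h <- hemo_params()
  P <- seq(40, 200, by = 0.5)
  Z <- pressure_to_impedance(P, h)
  expect_true(all(diff(Z) < 0))
})

test_that("closed-form area response matches Euler integration of the
           pressure-area coupling", {
  h <- hemo_params()
  # one simulated beat sampled at 0.1 ms, integrated forward in time:
  # dA = A * dP * PTT^2 / (rho * D^2), pressures in Pa
  pulse <- pressure_pulse(n_beats = 1, fs = 10000, sbp = 120, dbp = 70,
                          heart_rate = 1.2, jitter_sd = 0)
  P_pa <- pulse$P * 133.322
  beta <- h$PTT^2 / (h$rho * h$D^2)
  A0_at_start <- pressure_to_area(pulse$P[1], h)
  A_euler <- numeric(length(P_pa))
  A_euler[1] <- A0_at_start
  for (i in 2:length(P_pa)) {
    A_euler[i] <- A_euler[i - 1] * (1 + beta * (P_pa[i] - P_pa[i - 1]))
  }
  A_closed <- pressure_to_area(pulse$P, h)
  expect_lt(max(abs(A_euler - A_closed) / A_closed), 0.01)
})

test_that("small pressure steps give the linearized relative area change", {
  h <- hemo_params()
  beta_mmhg <- h$PTT^2 / (h$rho * h$D^2) * 133.322
  for (dP in c(0.1, 0.5, 1)) {
    rel <- pressure_to_area(h$P0 + dP, h) / pressure_to_area(h$P0, h) - 1
    expect_equal(rel, beta_mmhg * dP, tolerance = 0.01)
  }
})

test_that("impedance inversion recovers pressure exactly", {
  h <- hemo_params()
  P <- c(56, 70, 90, 110, 120, 130)
  expect_equal(impedance_to_pressure(pressure_to_impedance(P, h), h), P,
               tolerance = 1e-9)
})

test_that("hemodynamic parameters must be positive", {
  expect_error(hemo_params(rho = -1), "positive")
  expect_error(hemo_params(A0 = 0), "positive")
  expect_error(pressure_to_impedance(c(120, NA), hemo_params()), "finite")
})

test_that("pressure pulse hits the assigned systolic and diastolic values", {
  for (bp in list(c(120, 70), c(111, 57), c(129, 78))) {
    p <- pressure_pulse(n_beats = 1, fs = 500, sbp = bp[1], dbp = bp[2],
                        heart_rate = 1.2, jitter_sd = 0)
    expect_lt(abs(max(p$P) - bp[1]), 0.1)
    expect_lt(abs(min(p$P) - bp[2]), 0.1)
  }
  # per-beat extrema with several beats and jitter
  p <- pressure_pulse(n_beats = 5, fs = 500, sbp = 120, dbp = 70,
                      heart_rate = 1.2, seed = 4, jitter_sd = 0.02)
  bounds <- c(p$beat_onset, length(p$P) + 1L)
  for (b in 1:5) {
    seg <- p$P[bounds[b]:(bounds[b + 1] - 1)]
    expect_lt(abs(max(seg) - 120), 0.1)
    expect_lt(abs(min(seg) - 70), 0.1)
  }
})

test_that("pulse train is periodic with the requested number of beats", {
  p <- pressure_pulse(n_beats = 5, fs = 500, sbp = 120, dbp = 70,
                      heart_rate = 1.2, jitter_sd = 0)
  expect_length(p$beat_peak, 5)
  # zero jitter: consecutive beats are identical sample sequences
  n_b <- diff(p$beat_onset)[1]
  expect_true(all(diff(p$beat_onset) == n_b))
  b1 <- p$P[p$beat_onset[1]:(p$beat_onset[2] - 1)]
  b2 <- p$P[p$beat_onset[2]:(p$beat_onset[3] - 1)]
  expect_identical(b1, b2)
})

test_that("pressure pulse rejects inadequate sampling rates", {
  expect_error(pressure_pulse(n_beats = 1, fs = 20, sbp = 120, dbp = 70,
                              heart_rate = 1.2), "sampling error")
})

test_that("beat morphology is monotone in the driving pressures", {
  sbp <- seq(105, 135, by = 1)
  w <- vapply(sbp, function(s) beat_morphology(s, 70)$sigma_sys, 0)
  expect_true(all(diff(w) >= 0))
  dbp <- seq(50, 85, by = 1)
  a <- vapply(dbp, function(d) beat_morphology(120, d)$dicrotic_amp, 0)
  expect_true(all(diff(a) >= 0))
})

test_that("measurement noise achieves the requested SNR", {
  p <- pressure_pulse(n_beats = 10, fs = 500, sbp = 120, dbp = 70,
                      heart_rate = 1.2, jitter_sd = 0)
  Z <- pressure_to_impedance(p$P, hemo_params())
  for (snr in c(10, 20, 30)) {
    out <- add_measurement_noise(Z, fs = 500, snr_db = snr, seed = 1,
                                 wander_rel = 0)
    measured <- 10 * log10(stats::var(Z) / mean((out - Z)^2))
    expect_lt(abs(measured - snr), 1)
  }
})

test_that("noise-free path returns the input unchanged and is reproducible", {
  Z <- sin(seq(0, 10, by = 0.01)) + 100
  expect_identical(add_measurement_noise(Z, fs = 100, snr_db = Inf,
                                         wander_rel = 0), Z)
  a <- add_measurement_noise(Z, fs = 100, snr_db = 20, seed = 7)
  b <- add_measurement_noise(Z, fs = 100, snr_db = 20, seed = 7)
  expect_identical(a, b)
  expect_error(add_measurement_noise(Z, fs = 100, wander_freq = 0.5), "0.3")
})

test_that("subject generation respects the configured ranges and seed", {
  for (s in 0:5) {
    prof <- generate_subject(seed = s)
    expect_gte(prof$baseline_SBP, 110)
    expect_lte(prof$baseline_SBP, 130)
    expect_gte(prof$baseline_DBP, 56)
    expect_lte(prof$baseline_DBP, 79)
    expect_gt(prof$baseline_SBP, prof$baseline_DBP)
    expect_gte(prof$heart_rate, 0.67)
    expect_lte(prof$heart_rate, 3.33)
  }
  expect_identical(generate_subject(seed = 3), generate_subject(seed = 3))
  expect_error(subject_config(sbp_range = c(100, 100)), "configuration error")
  expect_error(subject_config(sbp_range = c(60, 70), dbp_range = c(80, 90)),
               "configuration error")
})

test_that("protocol emulation produces the requested trial structure", {
  prof <- generate_subject(seed = 2)
  d1 <- emulate_protocol(prof, n_trials = 1)
  expect_length(d1$trials, 1)
  d <- emulate_protocol(prof, n_trials = 4)
  expect_length(d$trials, 4)
  for (tr in d$trials) {
    expect_length(tr$signal, length(tr$t))
    expect_length(tr$cuff_SBP, 1)
    expect_length(tr$cuff_DBP, 1)
  }
  # determinism: bit-identical datasets from the same profile
  expect_identical(emulate_protocol(prof, n_trials = 3),
                   emulate_protocol(prof, n_trials = 3))
})

test_that("degenerate noise settings collapse cuff values onto the baseline", {
  prof <- generate_subject(seed = 1)
  d <- emulate_protocol(prof, n_trials = 5, noise = FALSE)
  for (tr in d$trials) {
    expect_equal(tr$cuff_SBP, prof$baseline_SBP)
    expect_equal(tr$cuff_DBP, prof$baseline_DBP)
  }
})

test_that("noise-free impedance extrema invert to the latent pressures", {
  prof <- generate_subject(seed = 4)
  d <- emulate_protocol(prof, n_trials = 2, noise = FALSE)
  for (tr in d$trials) {
    # per-beat extrema of the raw impedance map onto SBP (minimum, artery
    # dilated) and DBP (maximum) through the closed-form inversion
    sbp_hat <- impedance_to_pressure(min(tr$signal), prof$hemo)
    dbp_hat <- impedance_to_pressure(max(tr$signal), prof$hemo)
    expect_lt(abs(sbp_hat - tr$true_SBP), 0.1)
    expect_lt(abs(dbp_hat - tr$true_DBP), 0.1)
  }
})

test_that("subject datasets round-trip through the CSV/JSON writer", {
  dir <- withr::local_tempdir()
  prof <- generate_subject(seed = 6)
  d <- emulate_protocol(prof, n_trials = 3)
  write_subject_dataset(d, dir)
  back <- read_subject_dataset(dir, prof$subject_id)
  expect_equal(back$profile$baseline_SBP, prof$baseline_SBP)
  expect_length(back$trials, 3)
  for (i in 1:3) {
    expect_equal(back$trials[[i]]$signal, d$trials[[i]]$signal)
    expect_equal(back$trials[[i]]$cuff_SBP, d$trials[[i]]$cuff_SBP)
  }
})
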