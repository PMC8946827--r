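---
title: "Personalized cuffless blood pressure from single-channel bio-impedance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized cuffless blood pressure from single-channel bio-impedance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the physical model
behind the simulator, every stage of the processing pipeline, the
regression network and its loss, the evaluation statistics, and — most
importantly — the design decisions taken where the problem was genuinely
open, with their rationale and limitations.

## 1. Physical model: from pressure to impedance

An electrode pair across a short carotid segment sees the impedance of a
cylindrical conductor, `Z = L / (sigma * A)`: segment length `L`, blood
conductivity `sigma`, lumen cross-sectional area `A`. The Bramwell–Hill
relation ties the area to transmural pressure,
`dP = rho * (D / PTT)^2 * dA / A`, with blood density `rho`, inter-site
distance `D` and pulse transit time `PTT`.

Treating `rho`, `D`, `PTT` as subject constants over a pulse, the relation
integrates exactly to

```
A(P) = A0 * exp((P - P0) * PTT^2 / (rho * D^2))      (pressures in Pa)
```

which the simulator uses as a closed form (`pressure_to_area()`), checked
in the tests against a brute-force Euler time-marching of the differential
form to within 1 %. Composed with Ohm's law this makes impedance strictly
decreasing in pressure: systole is an impedance *minimum*. The pipeline
therefore negates the filtered signal before peak detection so that the
systolic anchor is a positive peak; this sign convention is internal and
invisible to users of `extract_beats()`.

Pressure is user-facing in mmHg everywhere; the physics converts to pascal
internally (1 mmHg = 133.322 Pa).

Default hemodynamic constants (`hemo_params()`) are order-of-magnitude
carotid values: `rho` = 1060 kg/m³, `D` = 0.15 m travelled in
`PTT` = 25 ms (pulse-wave velocity 6 m/s), `L` = 2 cm, `sigma` = 0.6 S/m,
`A0` = 3e-5 m² at `P0` = 90 mmHg. Real neck IPG has a much smaller
fractional impedance swing because tissue in parallel shunts the artery;
since every beat is min–max normalized before feature extraction, only the
waveform *shape* matters downstream and the absolute ohm scale is
deliberately left uncalibrated.

## 2. What the synthetic generator emulates — and what it does not

No measurement data ship with this package; the generator stands in for a
small resting human trial and defines the study conditions used throughout
the tests:

* per-subject baselines drawn uniformly from SBP 110–130 mmHg,
  DBP 56–79 mmHg (resting normotensive ranges), heart rate 0.9–1.5 Hz;
* between-trial variability of the latent true pressures: SD 3.5 mmHg
  (resting seated subject);
* cuff reference = truth + Gaussian error, SD 1.5 mmHg (oscillometric
  repeatability);
* protocol: 30 trials, each one cuff reading plus a continuous IPG segment
  with 5 + 4 beats around the cuff operating time → 150 (beat, reference)
  pairs per subject;
* measurement noise: additive white noise at 20 dB SNR plus a 0.1 Hz
  baseline-wander sinusoid at half the signal's peak-to-peak amplitude
  (below the 0.3 Hz filter edge, so pre-processing must remove it);
* sampling rate 500 Hz (>100 samples per beat at the fastest admissible
  heart rate).

The beat template is a two-Gaussian shape — systolic peak (phase 0.18)
plus dicrotic bump (phase 0.48) — min–max anchored per beat so the sampled
maximum/minimum equal that beat's systolic/diastolic pressure exactly.
Because per-beat amplitude normalization later removes pulse-pressure
amplitude, the template couples two *shape* parameters monotonically to
pressure (`beat_morphology()`): systolic width grows with SBP, relative
dicrotic amplitude grows with DBP. This is a modelling choice (real
carotid morphology covaries with pressure through wave reflection and
arterial stiffness, but no quantitative law is asserted); it gives the
regression model a recoverable morphology-to-pressure mapping with two
independent information channels, one per target.

What the simulator does **not** emulate: motion artifacts, electrode-skin
impedance drift, arrhythmia, inter-beat morphology variability unrelated
to BP, the 50 kHz carrier and its demodulation, and any systematic
cuff-versus-intra-arterial bias. Passing the end-to-end accuracy tests
therefore demonstrates that the pipeline recovers BP *under its own
generating assumptions* — a necessary correctness property, not evidence
of clinical accuracy on real subjects.

Latent true pressures are kept alongside the noisy cuff values in every
trial record so simulation studies can separate cuff error from model
error.

## 3. Pre-processing

**Bandpass.** The analog front end is emulated by a 4th-order Butterworth
bandpass, 0.3–5 Hz, covering the 0.67–3.33 Hz heart-rate band and its
first harmonics. Two numerical choices matter:

* *Second-order sections.* At 500 Hz sampling the 0.3 Hz corner makes the
  direct order-8 transfer-function polynomial numerically unstable (poles
  crowd the unit circle and the filtered output diverges). The filter is
  designed analytically — Butterworth prototype poles, lowpass→bandpass
  transform, bilinear transform with prewarping — and applied as four
  biquads (`butter_bandpass_sos()`), each benign in double precision.
  `bandpass_gain()` provides the closed-form magnitude response used as an
  independent oracle in the tests.
* *Zero phase.* The filter runs forward and backward (magnitude response
  squared, no phase distortion). The hardware original is causal; the
  offline zero-phase version is a deliberate deviation that preserves beat
  morphology for feature extraction. Short records are odd-reflection
  padded by three corner periods to suppress the highpass start-up
  transient.

**Segmentation.** Systolic peaks are local maxima above 0.4 x the robust
signal amplitude (98th percentile), selected greedily highest-first under
a minimum spacing constraint. The spacing is *period-aware*: the beat
period is estimated from the autocorrelation peak inside the heart-rate
band and the minimum spacing set to 0.6 of it. A fixed spacing of
`fs / max_hr` (0.3 s) admits the dicrotic bump as a spurious peak at low
heart rates; the autocorrelation estimate does not. Beats span
trough-to-trough around each peak.

**Five-beat selection.** The protocol pairs one cuff reading with five
beats "around" the cuff operating time. The exact rule being unspecified,
the package selects the `k` beats whose systolic anchors are nearest the
cuff time, ties resolved toward the earlier beat, output in time order
(`select_trial_beats()`). Strictly-before, strictly-after or mixed
windows are all special cases of nearest-`k` for the simulated geometry.

**Normalization.** Each beat is linearly resampled to 128 samples and
min–max scaled to [0, 1]; a constant beat maps to the zero vector. This
removes the unknown (and here uncalibrated) front-end gain; all BP
information must survive in shape.

## 4. Scalogram features

Each beat becomes a continuous-wavelet-transform magnitude scalogram. The
Daubechies-8 wavelet is a discrete-family wavelet with no closed-form
mother function, so the CWT is implemented by cross-correlating the beat
with rescaled copies of the cascade-algorithm approximation of the db8
wavelet (`wavelet_function()`, eight refinement levels, unit L2 norm,
kernels L2-normalized per scale). The hardcoded 16-tap scaling filter is
verified in the tests against its defining properties (sum sqrt(2), unit
norm, even-shift orthogonality, vanishing moments of the cascade wavelet).
A real Morlet wavelet is available as an analytic alternative
(`wavelet = "morlet"`).

Default scales: 64 log-spaced values whose pseudo-frequencies span
0.5–20 Hz at the normalized beat's effective sampling rate (128 samples
per nominal 0.8 s beat) — the pulse fundamental and its morphology-bearing
harmonics. Neither the scale set nor the image resolution is a physical
constant; both are configuration. The magnitude (not signed) coefficients
are used: after per-image normalization the sign carries no extra
morphology information for a single-channel image input. Scalograms are
bilinearly resized to 32 x 32 and min–max normalized to [0, 1].

## 5. The regression network

`build_ssrnet()` instantiates a compact two-stream convolutional network
with a soft stagewise regression head — a bounded-regression architecture
in which the prediction is assembled from progressively refined soft bin
assignments rather than a single linear output:

* two parallel trunks of 3 stages; each stage is a 3 x 3 convolution
  (8 channels) followed by ReLU + 2 x 2 average pooling in one stream and
  tanh + 2 x 2 max pooling in the other (complementary feature statistics);
* per stage, each stream's map passes a 1 x 1 convolution (4 channels),
  activation, and average pooling to 4 x 4; the two 64-vectors are fused
  by elementwise product;
* from the fused vector each stage emits soft bin probabilities
  `p` (softmax over `s_k = 3` bins), a bounded bin-width refinement
  `delta` (tanh, scaled by 0.5 so a stage can never collapse its effective
  bin count to zero), and per-bin shifts `eta` (tanh);
* the normalized prediction is the stagewise expectation

  ```
  y_norm = sum_k [ sum_i p_i(k) * (i + eta_i(k)) ] / prod_{j<=k} s_j * (1 + 0.5 * delta_j)
  ```

  clamped to [0, 1] and mapped onto the regression span (`bp_range`,
  default 80–180 mmHg systolic, 40–120 mmHg diastolic — printed resting
  ranges with margin). Predictions are bounded by construction.

The default instantiation has 4 077 trainable parameters (0.004 M), an
order of magnitude below the 0.04 M budget that `build_ssrnet()` enforces
as a hard error. Forward pass, back-propagation and Adam are implemented
in vectorized R (BLAS matrix products via gather-based im2col); at this
parameter count a deep-learning framework would be slower to load than
the training takes to run. Gradients are verified against central finite
differences in the test suite. The systolic and diastolic targets get
independent networks — the pipelines are reported separately and weight
sharing is never assumed.

**Loss.** Training minimizes the quartile-weighted penalized MAE: per
sample `|pred - cuff| * alpha` if the cuff reference lies strictly below
Q1 or strictly above Q3 of the *training* reference distribution
(quartiles by R's type-7 linear interpolation), else `|pred - cuff|`;
references exactly on a quartile take the unweighted branch (the weighted
branch is defined by strict inequalities). `alpha = 1` reduces exactly to
plain MAE. Up-weighting the distribution tails (default `alpha = 3`)
pushes the model to fit the rarer high/low pressures early, which is what
accelerates convergence.

**Optimizer and schedule.** Adam, learning rate 1e-3, batch size 16,
default 100 epochs. None of these are physical constants; they are
config-exposed defaults chosen because the training loss on the study
conditions plateaus well within 100 epochs at this learning rate.
Training is deterministic given a seed (initialization and per-epoch
shuffles both derive from it).

**Convergence epoch.** `convergence_epoch()` declares convergence at the
epoch of the last relative improvement of the running-best loss by at
least `rel_tol` (default 2 %), provided at least `patience` (default 10)
further epochs were observed past it. A first-plateau rule was rejected:
Adam warm-up can stall the loss for ten epochs *before* most of the
descent, which would absurdly date convergence at epoch 1. Under the
adopted rule a flat history converges at epoch 1 and a history still
improving at its end returns `NA` (treated as right-censored in the
penalty-weight comparison).

When convergence is compared *across* penalty weights, it is measured on
the unweighted training-MAE curve (`mae_history`, recorded every epoch
alongside the penalized loss). The penalized losses for different `alpha`
are different objectives with different noise levels: the `alpha = 3`
loss has roughly twice the variance, so its running best keeps logging
small improvements later purely as a noise artifact, which would bias any
direct comparison against the penalty. On the common MAE scale the
penalty's effect is what the loss design intends — the tails of the
reference distribution are fitted earlier and the model reaches its
plateau in fewer epochs. Only the *ordering* of median convergence epochs
across `alpha` values is asserted in the tests, never an absolute epoch.

## 6. Evaluation battery

With cuff reference `x_i` and prediction `y_i` over `n` test pairs:
`ME = mean(y - x)`, `MAE = mean(|y - x|)`, each reported ± the sample
(n−1) SD of the per-pair quantity; Bland–Altman bias (= ME) with
1.96 SD limits of agreement and the per-pair (mean, difference) table;
box/quartile summaries via the same type-7 quartile convention; and the
AAMI verdict `|ME| <= 5 mmHg and SD <= 8 mmHg` (bounds inclusive).

**Split.** 150 pairs divide into 120 training and 30 test pairs. The five
beats of a trial share one cuff label, so a beat-level random split would
leak test labels into training; `split_dataset()` therefore samples whole
trials (6 test trials x 5 beats), stratified, seeded, stricter than a
naive random split. Whether the original protocol split randomly or
chronologically is unknown; the seeded random trial-level split is this
package's documented choice.

## 7. Problem sizes and runtime envelope

Chosen so the full test suite and the acceptance script run comfortably
on one CPU core:

* default training: 100 epochs, ~0.5–0.7 s per epoch at 32 x 32 inputs;
* the end-to-end accuracy test trains both targets for 60 epochs (the
  loss plateau is well established by then; the acceptance script uses
  the full 100-epoch default);
* the penalty-weight convergence comparison uses 10 seeds x 2 alpha
  values x 60 epochs on the shared default-subject fixture, with
  not-yet-converged runs censored at 61 epochs;
* property-style tests (segmentation recall/precision) use 100 random
  subjects at one trial each.

## 8. Known limitations

* The morphology–pressure coupling is monotone-linear by construction;
  real carotid waveforms encode pressure nonlinearly and non-stationarily,
  and per-subject recalibration cadence is untested.
* The db8 "CWT" is the cascade-approximation cross-correlation used by
  common toolboxes, not a true continuous-wavelet integral (db8 has no
  continuous closed form); scales below ~2 samples are aliased by design.
* The parameter budget is enforced, but model size in kilobytes and
  inference latency are serialization- and hardware-dependent and are out
  of scope.
* With 30 test pairs the SD of the error SD is substantial; single-seed
  accuracy numbers carry Monte-Carlo noise of a few tenths of a mmHg.
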