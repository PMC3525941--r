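---
title: "Auditory streaming BCI analysis: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory streaming BCI analysis: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streambci)
```

## The paradigm

In a two-class auditory streaming BCI, the user hears two simultaneous
periodic tone streams, one per ear, and chooses between two options by
covertly attending to one stream. Attention modulates the event-related
potential (ERP) evoked by every tone of the attended stream — the N1 around
100 ms is sharpened and the late positivity around 300 ms is enhanced — so a
classifier applied to stimulus-locked EEG can decode the attended side on a
single trial of a few seconds. Two stream geometries are in use:

* **Fixed phase (FP)**: both streams have a 492.2-ms stimulus-onset
  asynchrony (SOA) and the right stream is offset by exactly half a period
  (246.1 ms). The unattended stream's response appears at a constant latency
  inside every attended-locked epoch.
* **Drifting phase (DP)**: the right stream's SOA is lengthened to 546.9 ms
  (initial cross-stream lag 109.4 ms), so the relative phase of the streams
  drifts by 54.7 ms per beat, and the unattended response smears across
  latencies in the stream-locked average.

A trial holds 8 left and 7 right tones; the first two of each stream are
excluded from analysis (attention takes a moment to settle, and those epochs
lack preceding-stimulus overlap). Standards are amplitude-modulated to 100%
depth at 256/6 Hz (left) and 256/7 Hz (right) — chosen so the modulation
period is an integer number of EEG samples at 256 Hz — while the targets the
listener counts (1–3 per stream, uniformly placed after the first two
stimuli) are unmodulated. An `FP500` variant (SOA 500 ms, offset 250 ms)
matches a session that used round numbers.

## The synthetic generator

`simulate_recording()` emulates exactly the statistical structure the
decoder assumes, nothing more:

* a **single-source biphasic ERP**, one negated sine cycle over 400 ms
  (negative peak 100 ms, positive peak 300 ms; `biphasic_wavelet()` warps
  the phase piecewise-linearly if other latencies are requested), convolved
  with the stimulus impulse train;
* an **attention gain** multiplying responses to attended-stream stimuli,
  default 1.2 (a 20% benefit);
* a **fixed spatial projection** of that source over the 16-channel montage
  (fronto-central maximum at Cz/Fz), so that spatial whitening and the
  multichannel classifier have realistic structure; with `n_channels = 1`
  and unit gain the generator reduces to the single-channel simulation used
  for design comparison;
* **pink (1/f power) noise**, independent per channel, rescaled so its SD is
  `sd_ratio` (default 2.0) times the SD of that channel's noiseless signal,
  the signal SD being measured over the stimulation interval (first onset to
  last response offset) of the recording. The 1/f spectrum reproduces the
  dominance of slow EEG fluctuations that the 0.1–8 Hz band-pass must
  contend with.

Trials are laid out in 5.5-s segments (0.5 s of silence before the sound
start; all stimulus onsets fall before 3.5 s, so every 600-ms epoch fits).
`simulate_gaze()` adds an optional behavioral confound: horizontal gaze
drifting exponentially toward the attended side from the cue (2.5 s before
the sound), with time constant 1.5 s — subjects who fail to hold fixation —
plus white measurement noise. `simulate_cohort()` draws per-subject
attention gain (1.1–1.3), noise ratio (1.5–2.5), and gaze drift (0–0.4
screen units) uniformly, representing a healthy-subject group centered on
the nominal 20%-gain / noise-ratio-2 condition.

What the generator deliberately omits: eye-blink and muscle artifacts,
non-stationary or spatially correlated noise, latency jitter by default
(`latency_jitter_sd_s` is exposed but 0), refractory effects at fast
stimulus rates, and any realistic forward head model. Passing tests
therefore show that the chain is *correct under its own assumptions* and
well-calibrated under the null; they do not certify performance on human
EEG, whose violations of these assumptions (artifacts, non-Gaussian noise,
varying ERP topographies) are exactly what the whitening and regularization
exist to absorb.

## The decoding chain

1. **Band-pass** 0.1–8 Hz, Butterworth of order 6 in the band-pass
   convention (6 pole pairs, 6th-order roll-off per skirt). The online
   filter is **causal** with state continuous across a run, as a real-time
   system must be; its group delay is accepted, since it shifts attended and
   unattended responses equally. For visualization and the r² time courses a
   **zero-phase** forward–backward variant (0.1–45 Hz) is used instead. The
   narrow normalized band makes the 12-pole transfer-function form
   numerically unstable, so the design is factored into cascaded biquads
   (analog prototype poles, band transform, bilinear transform per section,
   each section normalized at the band's geometric center); stability is
   checked per section and the design is rejected with a diagnostic if a
   pole leaves the unit circle.
2. **Epochs** of `floor(0.6 * fs)` = 153 samples at 256 Hz, the half-open
   window [onset, onset + 600 ms), one per retained stimulus (6 left + 5
   right per trial).
3. **Difference features** `X_Δ = mean(right-locked) − mean(left-locked)`,
   maintained as a running average within each trial (reset at trial
   boundaries). One snapshot is emitted per new epoch — 11 per FP trial,
   matching an online update rate of roughly 4/s; until a stream has its
   first epoch, its running mean is taken as zero, so early snapshots are
   informative but one-sided. Unequal final counts (6 vs 5) are handled by
   plain per-stream means.
4. **Whitening**: the spatial covariance of each training epoch (time mean
   removed per channel, n−1 denominator) is averaged over epochs, and
   `W = (Σ + ridge·I)^{−1/2}` is computed by symmetric eigendecomposition.
   The default ridge, `1e-6 · trace(Σ)/channels`, only guards rank
   deficiency; with `ridge = 0` whitened training epochs have identity mean
   covariance to machine precision. Whitening makes the subsequent isotropic
   L2 penalty meaningful across channels of very different variance and
   renders trial scores equivariant to invertible channel mixing.
5. **Classifier**: linear logistic regression on the whitened, flattened
   `X_Δ`, trained by L-BFGS on the convex penalized likelihood. Label +1 is
   attend-right (`X_Δ` is right-minus-left, so this is the natural sign).
   The features are divided by one global RMS scale computed on the training
   set, so the default `lambda = 1` acts on standardized whitened features;
   a scalar (rather than per-feature) scale preserves the mixing
   equivariance. The bias is not penalized. The trial prediction is the sign
   of the final snapshot's output, with an exact zero tie-broken to right
   (documented, measure-zero under the generator).
6. **Online protocol**: the classifier for run *k* ≥ 2 is trained on runs
   1..k−1; run 1 is never scored. Six 20-trial runs thus yield 100 scored
   trials per condition.
7. **Continuous control**: decoder outputs pass through an exponential
   moving average with decay 0.5 — implemented as the convex combination
   `y_k = 0.5 x_k + 0.5 y_{k−1}`, which has unit DC gain so the control
   signal keeps the classifier's scale (a plain geometric sum would double
   it) — then a causal 8th-order Butterworth low-pass at 3 Hz, then an
   affine gain/offset whose values are application-specific configuration.
   When outputs arrive slower than twice the cutoff (as with ~4 updates/s)
   the low-pass cannot be designed and is bypassed with a warning.

## Measurement layer

* `sensitivity_index()` implements
  `d_a = (μ_att − μ_unatt) / sqrt((σ²_att + σ²_unatt)/2)` with n−1 sample
  SDs (the conventional d_a definition; the denominator choice is not
  critical at the trial counts used).
* `signed_r2()` is the squared point-biserial correlation carrying the sign
  of the group difference, positive for attend-right.
* ERP regions of interest: N1 70–125 ms, P2 150–240 ms, P3 250–310 ms on
  grand averages; difference-wave windows 50–90, 120–190, 200–265 ms
  (the early attention-related negativity peaks before the N1 itself, and
  the last window is cut short to avoid contamination by the next
  stimulus's response).
* Exact tests are computed by enumeration, not approximation, at the sample
  sizes where they are used (cohorts of 8–16 subjects): the Wilcoxon
  signed-rank null distribution over all 2^n sign assignments (zeros
  dropped, mid-ranks for ties; two-sided p as the probability of a
  deviation from the null mean at least as large), Fisher's exact test by
  hypergeometric sums under the probability-mass two-sided rule, and
  Spearman's rho with the full n! permutation distribution for n ≤ 9.
  Beyond those sizes both Wilcoxon and Spearman switch to standard
  asymptotic approximations.

## Experiments

`snr_simulation()` reproduces the single-channel design comparison: for each
condition, 1000 attend-left and 1000 attend-right trials are generated,
preprocessed, and reduced to final `X_Δ` features; `d_a` is computed per
epoch sample across instances, and the summary is the ratio of the peak
|d_a| between FP and DP. "Up to N times higher" is operationalized as this
max-over-samples ratio. At the stated parameters the ratio comes out
around 2–2.7 across seeds — above 1 and consistent with an advantage of up
to about 3.

`experiment1_analog()` runs the full within-subject comparison on a
synthetic cohort and tests FP−DP accuracy differences with the exact
Wilcoxon test. `backward_playback()` reverses the recording while keeping
the event table, which destroys the stimulus–response correspondence and
provides an honest chance-level estimate for any downstream scoring.
`gaze_audit()` asks whether gaze could substitute for EEG: per subject it
extracts the peak r² of raw horizontal gaze over trial time, of gaze passed
through the identical preprocessing chain (band-pass, epoching, difference
of stream-locked averages), and of the preprocessed EEG at Cz, then
rank-correlates each with decoding accuracy. In the generator, gaze drift is
slow and smooth, so the stream-rate difference-of-averages chain suppresses
it — mirroring the argument that rhythmic eye movements, not static gaze,
would be needed to contaminate the decoder.

## Numerical choices and degenerate inputs

* Epoch length `floor(0.6·fs)` keeps the window half-open; at 256 Hz this is
  153 samples.
* Stimulus onsets are rounded to the nearest sample both for response
  placement and event markers.
* The anti-aliased sawtooth is synthesized additively up to Nyquist.
* `pink_noise()` shapes a white Gaussian spectrum by 1/sqrt(f) above the
  first nonzero FFT bin, zeroes DC, and rescales to the target SD exactly.
* Whitening with `ridge = 0` rejects a singular covariance with advice to
  set a ridge; `train_decoder()` rejects single-class input and non-finite
  features; `extract_epochs()` rejects epochs that overrun the recording,
  naming the offending events.
* Convexity makes retraining deterministic; the L-BFGS tolerances are tight
  enough that label-swap antisymmetry holds to 1e-6.

## Problem sizes

The test suite exercises reduced sizes chosen to keep the full suite around
two minutes while leaving every statistical check well-powered: cohorts of
3–16 subjects at 2 channels, runs of 8–20 trials, 120–1000 noise instances.
The acceptance script uses the full stated simulation (1000 instances per
class, 10 replicates) and a 500/500 train/test split for the null
calibration. The qualitative conclusions (FP > DP for nearly all subjects;
chance-level behavior under the null and under backward playback) are stable
across seeds at these sizes.

## Known limitations

* The generator's single fixed source cannot probe spatial-filter selection
  beyond whitening, per-subject topographies, or artifact robustness.
* The causal band-pass at 0.1 Hz has a very long impulse response; its
  startup transient spans the first trials of a run. The online protocol
  never scores run 1, which hides most of this; analyses of isolated short
  recordings should prefer the zero-phase variant.
* The continuous-control low-pass stage is bypassed at realistic epoch
  update rates (~4/s < 2 × 3 Hz); it becomes active only for faster control
  loops.
* Human-subject summary statistics (mean accuracies, gaze r² distributions,
  their rank correlations) cannot be reproduced without recordings; the
  package instead verifies the machinery by construction, calibration, and
  enumeration oracles.
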