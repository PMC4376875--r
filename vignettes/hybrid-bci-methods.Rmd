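---
title: "Methods: simulating and decoding a hybrid P300/SSVEP interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding a hybrid P300/SSVEP interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the signal model behind the package's synthetic
EEG generator, the decoding methods, the numerical conventions, and the
choices made where the design was genuinely open. It states no empirical
result beyond what the test suite itself computes.

## The paradigm

A *trial* starts with a 2 s cue indicating the target icon, followed by a
1 s pause. A background rectangle then starts to flicker and the oddball
stimulation begins 500 ms later: 10 *flashing sequences*, each flashing
the panel's 6 icons once in random order for a duration drawn uniformly
from 200–300 ms (the jitter prevents steady-state responses to the
flashes themselves). A 1 s pause ends the trial; a *run* is 12
consecutive trials, so one run takes about 19.5 s × 12 ≈ 3.9 minutes in
expectation. Flashes follow each other back-to-back with no
inter-stimulus gap. With one panel and 12 trials every icon is cued
twice; with two panels (flickering at 12 and 15 Hz, flash orders drawn
independently per panel) each of the 12 icons is cued once. The
single-panel flicker frequencies are the 60 Hz screen refresh divided by
7, 6, 5 and 4: 60/7 ≈ 8.57, 10, 12 and 15 Hz.

`make_schedule()` draws the cue order, flash orders and durations from a
single seed, so a schedule is fully reproducible. Whether the two panels'
flash streams are onset-synchronized is not constrained by the paradigm;
we schedule them independently by default and expose `sync_panels` for
the synchronized variant.

## The synthetic EEG generator

`simulate_recording()` renders a schedule into a 34-channel recording
(32 scalp channels of the 10–20 layout plus two mastoids) at 1024 Hz,
in microvolts, as a sum of three independent parts:

1. **Background noise.** Per-channel Gaussian noise with a 1/f^β
   amplitude spectrum (β = 1 by default, the classic EEG regime), mixed
   across scalp channels through a seeded random spatial smearing matrix
   whose rows are normalized to unit power. The smearing produces the
   inter-channel correlation that the Minimum Energy Combination filter
   exploits; without it, spatial filtering would be pointless. The
   default `noise_scale` of 8 µV RMS per channel is a typical broadband
   scalp-EEG noise level. Mastoids carry independent noise and no signal.
2. **Event-related responses.** Every flash of the cued icon (when the
   oddball stream is present) adds a template time-locked to flash onset:
   a positive Gaussian bump (the P300; default 5 µV peak at 350 ms,
   SD 60 ms, parieto-central topography peaking at Pz) plus a negative
   Gaussian bump (the early negativity; default 3 µV at 150 ms, SD 25 ms,
   parieto-occipital topography). Gaussians are the simplest shapes
   satisfying the components' sign and latency-band constraints.
   Non-target flashes evoke nothing by default; a small exogenous
   response can be enabled with `nontarget_erp_scale`.
3. **Flicker responses.** Every panel with an active flicker adds
   `Σₖ Aₖ sin(2π k f t + φ)` for harmonics k = 1..3, gated from flicker
   onset to trial end, scaled by an occipital topography peaking at Oz.
   The phase φ is drawn once per trial and panel, uniform on [0, 2π).
   Harmonic amplitude triplets may differ per stimulation frequency
   (`ssvep_harmonic_amplitudes` as a named list), reflecting the
   empirical fact that the strongest harmonic varies across subjects.
   The attended panel's amplitudes are multiplied by `attention_gain`
   (default 1.5); unattended panels stay at base amplitude. The
   generator refuses frequencies whose third harmonic reaches Nyquist.

The defaults describe a typical responsive subject of a visual-BCI
study. Two named regimes are used as test fixtures: a *strong responder*
(P300 6 µV, harmonic amplitudes 2/1/0.5 µV, attention gain 2), matching
a strongly responsive participant, and a *silent subject* with all
amplitudes zero, for chance-level checks. These were fixed once when the
generator was written.

**What the generator does not emulate:** ocular and muscle artifacts are
off by default (an optional square-pulse frontal transient exercises the
rejection operator only), electrode drift and impedance changes, trial-
to-trial latency jitter or habituation of the ERP, nonlinear interactions
between the flicker and oddball responses, and non-stationary alpha
rhythms. Passing tests on this generator therefore show that the
pipeline recovers the structure it assumes — linear superposition of
templates and stationary correlated noise — not that it would reach the
same accuracies on real recordings.

## Preprocessing

The order of operations is reference → filter → epoch → (reject) →
resample. Referencing subtracts the mastoid mean from every scalp
channel. Two zero-phase Butterworth paths are used: 0.5–20 Hz, order 3,
for the ERP/decoding path, and a 0.2 Hz high-pass, order 4, for the
SSVEP path (decimated to 128 Hz and 256 Hz respectively). Filters are
applied forward and backward with reflective (odd-symmetric) edge padding
of three filter lengths — standard zero-phase practice; the low 0.2 Hz
cutoff means edge transients decay over seconds, which the padding
mitigates but does not remove entirely, so analysis segments sit well
inside a run.

Epoch windows are inclusive of both endpoint samples: (−0.2, 0.8) s at
1024 Hz gives 1025 samples, (0, 0.6) s at 128 Hz gives 77. Decimation
keeps every k-th sample starting from the first, so the 615-sample
0–600 ms epoch at 1024 Hz maps onto exactly the 77 samples at 128 Hz.

Artifact rejection scores each epoch by its maximum peak-to-peak
amplitude over channels and removes the `ceiling(0.10 n)` highest per
run, ties broken by removing the earlier epoch first. Rejection is
applied only in the ERP-averaging path; the classification path uses all
epochs. Whether epochs should be baseline-corrected before averaging is
left to the caller (no correction by default).

## P300 decoding

Epochs (0–600 ms, 128 Hz, all 32 scalp channels) are flattened
channel-major into 2464-dimensional vectors and classified target vs
non-target with a linear soft-margin SVM. The regularization constant is
chosen by an inner stratified cross-validated line search over a
logarithmic grid (default 15 points over 10⁻⁵–10², 10 inner folds,
accuracy criterion, ties to the smaller constant), then the model is
refit on the full training set. No class rebalancing is applied despite
the 1:5 target/non-target ratio, and all five non-cued icons contribute
non-target epochs.

Implementation notes: the SVM is solved by `kernlab::ksvm` on a
precomputed linear Gram matrix, normalized to unit mean diagonal — a
global feature rescale that the logarithmic grid absorbs — with SMO
tolerance 0.01; this keeps the solver well conditioned on
microvolt-scale inputs and makes the line search cheap. The explicit
weight vector is recovered from the support-vector coefficients and
oriented so larger decision values mean "target". Because the decision
function is affine, averaging epochs then scoring equals scoring then
averaging; trial scoring averages each icon's epochs over the first
*N_r* repetitions and detects the argmax icon, exact ties going to the
lowest icon id (flagged).

Evaluation is run-level: 3-fold cross-validation by run for the
single-panel design (train on 2 runs, test every trial of the third,
rotating: 36 correctness values per repetition count with 12-trial
runs), and train-on-the-first-2 / test-on-6 for the two-panel design
(72 values). In the two-panel design the decoder always scores the
cued panel's 6 icons.

## SSVEP detection

The narrow-band power of a single-channel segment at frequency f is the
squared projection onto the sine and cosine at f (`narrowband_power()`); for a
unit-amplitude sinusoid over an integer number of cycles it equals 0.25,
and it coincides with the squared DFT coefficient magnitude divided by
n² at on-grid frequencies.

For detection, the Minimum Energy Combination filter is fit per analysis
segment: the joint sinusoid basis of both candidate frequencies (sine
and cosine at k·f, k = 1..3) is projected out by least squares; the
residual's channel covariance is eigendecomposed; eigenvalues below
10⁻¹² of the largest are discarded as numerically null; the components
with the smallest eigenvalues are kept until their cumulative share of
the residual energy would exceed 10% (at least one), each eigenvector
scaled by 1/√eigenvalue. The SNR at a harmonic is its narrow-band power
divided by the mean power over the 8 nearest off-target bins on the
segment's frequency grid, excluding every candidate's harmonics; a
zero noise estimate yields an Inf sentinel with a warning. The
bin-average noise estimator is deliberately simpler than the
autoregressive noise model of the original spatial-filtering literature;
anyone comparing against that method should note the deviation. A
candidate's score is the mean SNR over components and harmonics 1–3;
the winner is the argmax, exact ties going to the lower frequency.

The analysis segment starts at oddball onset and spans 1.5·*N_r* s, the
nominal duration of *N_r* flashing sequences. The simulator gates the
flicker up to trial end (through the post-pause), so the segment is
always covered even when the randomized flash stream runs shorter than
its 1.5 s/sequence expectation.

The subject-trained variant keeps the three harmonic SNRs as a feature
vector per (trial, candidate) — labelled by whether the candidate was
attended — and fits a linear SVM with leave-one-out cross-validated line
search; at test time the candidate with the highest model output wins.
With equal information in every harmonic this reduces to (a monotone
transform of) the unweighted average, so it can only help when harmonics
differ in informativeness.

## Fusion and information transfer

The hybrid selection is correct only when both detectors are correct — a
logical AND, so hybrid accuracy is bounded by both marginals. The
bits-per-symbol of an N-ary selection with accuracy p is
B = log₂N + p·log₂p + (1−p)·log₂((1−p)/(N−1)), evaluated by continuity
at p ∈ {0, 1}. B is convex in p with its minimum of exactly 0 at chance
(p = 1/N) and rises again below chance — a known artifact of this
definition; the package reports below-chance values as-is with a
warning rather than clamping. The information transfer rate is
I = B · N_c / Σtᵢ · 60 bits/min with tᵢ = 1.5·*N_r* s per trial:
stimulation time only, excluding cue and pauses, so the curves isolate
decoding efficiency from interface overhead. Symbol counts are N = 6
(P300, icons within the cued panel — P300 accuracy deliberately ignores
the SSVEP outcome), N = 2 (SSVEP, panel choice) and N = 12 (hybrid).

## Problem sizes in the test suite

The tests exercise every operation at reduced scale, chosen so the suite
completes in minutes: synthetic subjects use 6–12 trials per run and 1–5
flashing-sequence repetitions instead of 12 × 10, and the decoder line
search uses a 3-point grid with 3 inner folds. The structural counts (36
and 72 correctness values per repetition count, 12 power values per
frequency-by-type cell) are verified at the full 12-trial shape. The
properties checked — chance-level accuracy at zero signal amplitude,
high accuracy for the strong-responder fixture, the AND bound, the
null effect of the oddball stream on flicker power — do not depend on
the reduced sizes beyond wider confidence bands, which the tests
account for.

## Known limitations

- The generator's linear-superposition assumption cannot probe the
  nonlinear stimulus interactions that motivate hybrid-interference
  studies in the first place; it reproduces their *structure*, not their
  physiology.
- MEC component selection with near-isotropic noise retains a single,
  effectively random component that may be orthogonal to the signal
  topography; this is inherent to the method, which presumes spatially
  structured noise.
- The 0.2 Hz high-pass has multi-second transients; analyses near run
  edges would need longer padding or discarded margins.
- Group-level inference on ERP correlations (mixed models, post-hoc
  contrasts) is intentionally out of scope; the package exports tidy
  tables for external statistical software instead.
- Real-data ingestion (BDF/EDF) is not implemented; recordings
  serialize to a plain-text container, and large runs are meant to be
  regenerated from seeds rather than stored.
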