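---
title: "Detecting movement intention from movement-related cortical potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting movement intention from movement-related cortical potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcpdetect)
```

## The problem

The movement-related cortical potential (MRCP) is a slow negative EEG
deflection that develops up to about two seconds before a self-initiated,
imagined or attempted movement. Detecting it before the movement itself
starts makes the MRCP a usable control signal for brain-computer interfaces
in neurorehabilitation, where an assistive device must be triggered within
the narrow window that supports Hebbian-like plasticity. The question this
package operationalises is a methods question: which single-channel feature
set — temporal MRCP morphology, or broadband spectral power — separates
pre-movement epochs from idle ("noise") epochs best, and how do both compare
to classic template matching?

Because no public recording of the original cue-based dorsiflexion protocol
exists, the package ships a seeded generator that emulates the protocol's
statistical structure, so that every stage of the pipeline is testable
end-to-end without any data download. The generator is a first-class,
tested module, not a fixture.

## The synthetic protocol

`generate_recording()` lays out two blocks of 50 cued trials (tasks `f60`:
ramp to 60% of maximum voluntary contraction in 0.5 s, and `s20`: ramp to
20% in 3 s), with 10 s between cues so that the noise window (−5…−3 s) and
the force-baseline window (−4…−2 s) always fit inside a trial. Each of the
ten 10-20 channels receives:

* **pink background noise** — white noise spectrally shaped to a 1/f power
  profile (DC bin zeroed) and rescaled to a per-channel standard deviation
  of 2 µV, independently per channel;
* **an alpha oscillation** — a 10 Hz sinusoid of 1 µV amplitude with a
  random phase per channel;
* **the MRCP** — a half-cosine ramp from 0 to −10 µV over the 2 s before
  the movement onset, followed by a half-cosine recovery (the post-onset
  shape is irrelevant: epochs end at onset). The half-cosine was chosen
  because it is smooth with zero-derivative endpoints; the literature
  constrains only the morphology (a monotone slow negativity), not an
  equation.

The MRCP is scaled per channel: gain 1.0 at Cz, 0.4 on the surrounding
eight electrodes, 0 at FP1 (which carries EOG). This guarantees that the
large-Laplacian surrogate channel retains a net MRCP gain of
1.0 − 0.4 = 0.6. Scalp topography is otherwise unreported for this montage,
so the simple peaked profile is the least-assumption choice.

The true movement onset trails the visual cue by a uniform 0–0.3 s reaction
delay, which makes force-based onset detection non-trivial. The force trace
is a linear ramp to the task target (constant-rate, matching the cued
task), a 0.5 s plateau, and a release, plus Gaussian noise with standard
deviation 5×10⁻⁴ of MVC — quiescent torque-transducer noise. That noise
level matters: the onset rule below requires 200 ms of samples *all* above
baseline, so the detection latency is roughly where the ramp clears ~3.3
noise standard deviations. At s20's slope (0.067 MVC/s) a noise sd of
5×10⁻⁴ puts that point ~25 ms after onset, comfortably inside the 50 ms
recovery the pipeline is validated against; a ten-fold noisier force sensor
would push s20 detections hundreds of milliseconds late no matter how the
rule is implemented. Physiological tremor during contraction is not
modelled — it starts after onset and does not affect the baseline or the
detection point.

For imaginary movements the force trace stays at baseline noise and the
task onset is the cue itself; a guard verifies that no force was actually
produced (flagging trials whose force exceeds baseline by more than 5%
MVC).

What the generator does **not** emulate: eye blinks and other artifacts,
electrode impedance drift, spatially *correlated* background EEG (each
channel's background is independent, so the Laplacian cancels the MRCP
common mode but gains nothing against the background), session
non-stationarity, and lesioned topographies. Passing tests therefore show
that the pipeline recovers what the model injects under realistic noise
power — not that it reproduces human-subject performance figures.

## Preprocessing

Nine scalp channels are combined into one surrogate channel by a large
Laplacian: Cz minus the mean of F3, Fz, F4, C3, C4, P3, Pz, P4. With nine
electrodes the eight non-central ones are the only available ring, so the
weights are +1 and eight times −1/8; they sum to zero, making the surrogate
exactly invariant to reference shifts. The surrogate is then filtered along
two paths, both 2nd-order Butterworth applied forward and reverse (zero net
phase): 0.05–10 Hz band-pass for the temporal path (MRCP morphology and the
template), and 0.05 Hz high-pass for the spectral path (broadband power).
The spatial filter is applied before the temporal filters; by linearity the
order is irrelevant, and filtering one channel instead of nine is cheaper.

Numerical choices: filters are applied after odd-reflection padding of
three times the slowest corner's effective impulse length (~3/0.05 s);
epochs are always cut well inside the recording, so edge transients never
reach them. The high-pass family and order are not dictated by the temporal
band-pass; 2nd-order Butterworth was chosen for symmetry.

## Epochs

Movement onset is the first sample at or after the cue for which every
sample of the following 200 ms window strictly exceeds the baseline (mean
force 2–4 s pre-cue). "Exceeds" is implemented literally — no
standard-deviation margin — with an optional `margin_sd` knob. Onsets are
found on the 2000 Hz force clock and mapped to the nearest 500 Hz EEG
sample by rounding. Per trial, the signal epoch is the half-open window
[onset − 2 s, onset) and the noise epoch [onset − 5 s, onset − 3 s); with
0-based start indices `round(t·fs)`, a 2 s epoch at 500 Hz is exactly 1000
samples, and the two windows are separated by exactly 1 s. Trials whose
onset cannot be found, or whose windows leave the recording, are dropped
and logged.

## Features

**Temporal** (from the 0.05–10 Hz path), executed-movement mode: time of
the minimum sample (ties to the earliest), mean amplitude, slope and
intercept of an OLS line over the whole epoch, and slope and intercept of
an OLS line over the final 0.5 s. Imagery mode drops the two intercepts and
adds the mean of the final 0.5 s (five features). Two ambiguities are
resolved by switches with documented defaults: the endpoint of the
full-epoch regression is the epoch end (the detection point coincides with
movement onset), with `regression_end = "max_negativity"` as the
alternative reading; and "point of maximum negativity" is encoded as a
latency, since amplitude is already represented by the mean features.

**Spectral** (from the 0.05 Hz high-pass path): Welch power spectral
density with 1 s Hamming segments at 50% overlap (three segments per epoch,
1 Hz resolution — the 0–4 Hz band then holds four bins), averaged into five
band powers: 0–4, 4–8, 8–13, 13–30, 30–100 Hz. Band edges are half-open so
shared edges are never double-counted; the last band includes 100 Hz. The
PSD is one-sided density (µV²/Hz); any fixed scaling convention would do,
since LDA is affine-invariant per feature, but this one is stated for
reproducibility.

## Detectors and evaluation

The LDA is solved in closed form: pooled within-class covariance with equal
priors (classes are balanced by construction), ridge-regularised by
`1e-6·trace(S)/d` on the diagonal when ill-conditioned; an epoch is called
movement iff its discriminant score is strictly positive. The template
detector averages the training movement epochs pointwise and classifies by
Pearson correlation against a threshold fitted on a fixed grid (−1 to 1,
step 0.01) minimising training error, ties resolved toward the lower
threshold (favouring sensitivity).

The nested five-fold test: epochs are split into five class-stratified
parts by a seeded shuffle (the original description does not state
stratification, but unbalanced parts would distort error comparisons).
For each test part, the remaining four parts undergo a 4-fold validation
rotation; the already-trained model with the lowest validation error (ties:
lowest part index) is applied *unchanged* to the test part — it is not
refit on all four parts. Detection error, sensitivity and specificity are
reported per fold and as their arithmetic means.

Cohort-level comparison uses the Friedman test on per-subject mean errors:
temporal vs spectral features first, then the better of the two vs template
matching, at a 0.05 significance level, with results summarised as mean ±
standard error (sd/√n). For small untied tables (n ≤ 8 subjects, k ≤ 3
methods) the p-value comes from the exact permutation null of the statistic
(built by dynamic programming over per-subject rank permutations) rather
than the chi-square approximation, which is visibly off at such sizes; the
chi-square approximation is used otherwise. A three-class (f60 / s20 /
noise) Fisher discriminant projection is provided for feature-space
visualisation, with each output dimension rescaled to [−1, 1].

## Problem sizes and determinism

The cohort analyses in the test suite and the acceptance script use 12
synthetic subjects at the default 2 × 50 trials each (100 movement + 100
noise epochs per subject), the size at which per-method standard errors
across subjects are ~0.5 percentage points; sensitivity analyses (the
amplitude sweep) use 4-subject, 2 × 20-trial cohorts over several seeds,
which is sufficient to resolve the monotone error trend. All randomness
flows from explicit integer seeds threaded through the generator and the
fold assignment; two runs with the same configuration and seed produce
byte-identical reports.

## Known limitations

* With spatially independent background noise the Laplacian provides no
  noise-cancellation benefit, only MRCP contrast; real EEG background is
  spatially correlated, so the surrogate channel's real-world SNR advantage
  is understated.
* Under these conditions the broadband-power features are the *weakest* of
  the three methods (their delta-band power estimate carries large
  signal×noise cross-term variance at three Welch averages per epoch),
  whereas on human data spectral features are reported to be the strongest.
  This is a property of the synthetic noise model, not of the feature code
  — the band powers verify against independent PSD oracles.
* The pipeline is strictly offline: epochs are cut with knowledge of the
  onset. No sliding-window online detection, majority voting, artifact
  rejection, or multi-channel feature concatenation is implemented.
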