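---
title: "Multimodal signature + EEG authentication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal signature + EEG authentication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A handwritten signature is easy to capture on a phone and widely accepted,
but a practiced forger can reproduce its shape. Brain activity recorded
*while* signing is a different matter: the EEG rhythm that accompanies a
signing act is specific to the person producing it and cannot be observed,
let alone imitated, by watching the pen. neurosign implements an
authentication pipeline built on that asymmetry. Each enrollment sample is
a pair: the dynamic signature (a time-ordered sequence of pen coordinates)
and a simultaneous 14-channel EEG recording at 128 Hz. Two independent
sequence classifiers — one per modality — produce class posteriors that are
combined by decision fusion for identification, and compared against
per-identity thresholds for verification.

## Feature extraction

**Signature features (FS).** The trace is first normalized (first point at
the origin, bounding-box diagonal scaled to 1, aspect preserved) so that
device resolution and signing size drop out. Each point contributes one
frame `[x, y, alpha, beta]`: the normalized trajectory plus the local
writing direction. The direction at point *j* is the chord joining its two
neighbors `j-1` and `j+1`, summarized as the acute angle `alpha` the chord
makes with the x-axis and its complement `beta = 90 - alpha` with the
y-axis (degrees). As undirected line angles these are invariant to
traversal direction, translation and uniform scaling — properties the test
suite checks directly. Endpoints replicate the nearest interior frame's
angles so the frame count equals the point count; a zero-length chord (a
pen hold) carries the previous angles forward, with 0/90 used when a trace
opens with a hold. Whether the trajectory should enter the features raw or
normalized, and in which angular unit, are conventions of this package:
raw coordinates would leak device geometry into the classifier, and degrees
match how such angles are usually reported.

**EEG features (FD).** Each channel is analyzed with a short-time DFT:
frames of `N = 64` samples (0.5 s at 128 Hz) advancing by 32 samples (50%
overlap), tapered by the Hanning window `W(x) = alpha - (1-alpha) cos(2
pi x / N)` with `alpha = 0.5`, then transformed by `F_u = sum_x f_x
exp(-i 2 pi u x / N)` (computed with the FFT; the test suite holds it to
the naive O(N^2) sum within 1e-9). Band energies sum `|F_u|^2` over bins
whose center frequency lies inside each of the five canonical bands —
Theta 4–8, Alpha 9–12, Low Beta 13–16, High Beta 17–25, Gamma 26–40 Hz,
inclusive at both edges, Nyquist-capped. The feature sequence keeps only
the gamma band, one energy per channel per frame: gamma activity is the
band most strongly tied to individual identity in signing-type tasks.
Window length and overlap are package choices: 64 bins at 128 Hz give
2 Hz resolution, which covers the 26–40 Hz gamma band with 8 bins while
keeping enough frames per signing act for a sequence model. Energies are
log-compressed (`log(1 + E)`) because raw band energies span decades,
which destabilizes recurrent training.

## The sequence classifier

Both feature sequences are classified by a bidirectional LSTM: two
independent hidden layers (default 64 memory cells each) read the sequence
forward and backward, and a shared softmax output layer sees both at every
timestep, so each frame's output is conditioned on the entire sequence.
Training minimizes the cross-entropy `E = -sum_(x,z) sum_c z_c ln r_c`
with the sequence label replicated at every timestep and summed over the
sequence, by stochastic gradient descent: weights update after every
sequence, the presentation order is reshuffled each epoch, momentum is
0.9, the learning rate 1e-4, and initial weights are uniform in
[-0.1, 0.1]. A stratified validation split (one of every eight training
sequences per class) drives early stopping: training halts when the
validation error has not improved by more than `min_delta` for `patience`
consecutive epochs, and the best-validation weights are kept — fixed epoch
counts do not transfer between datasets, so a plateau criterion replaces
them. Elementwise gradient clipping (default ±1) guards the rare unstable
step; disable it with `grad_clip = 0`. Features are z-scored with
training-set statistics inside the model (angles in degrees and log
energies live on very different scales; the stored model carries the
transform). A sequence-level posterior is the arithmetic mean of the
per-timestep softmax vectors, renormalized — the least-commitment pooling
given per-timestep outputs, and the one whose normalization is testable.
The implementation is compiled (RcppArmadillo) with the training loop's
randomness (init, split, order) generated in R under explicit seeds, so
training is bit-reproducible.

## Decision fusion

For one test sample the two classifiers yield posterior vectors `P(w_j |
x_i)` over the m enrolled identities. Three combination rules are
implemented, each with deterministic lowest-index tie-breaking:

* **Sum rule** — fused score of class j is `sum_i P(w_j | x_i)`;
* **Borda count** — each classifier ranks classes by descending posterior;
  rank 1 earns m points, rank 2 earns m−1, and so on, ties sharing mean
  points (so the totals always conserve `R m (m+1)/2`); fused score is the
  summed points;
* **Max rule** — the class holding the single largest posterior over all
  classifiers and classes wins.

Each rule is verified against an independent brute-force enumeration
oracle on a thousand random posterior sets.

## Verification

A claim is a sample plus a claimed identity *i*. Its matching score is the
posterior that identity receives — per modality, or fused, with the fused
score normalized to [0, 1] by its rule-specific maximum (R for the sum
rule, R·m for Borda) so that all rules share the probabilistic threshold
domain. The claim is accepted iff the score *strictly* exceeds the
identity's threshold `th_i`. The default calibration policy is zero-FRR:
`th_i` sits `1e-6` below the smallest genuine calibration score, so every
calibration sample is accepted and the operating point has 100% TPR by
construction; security is then read from the false acceptance rate alone.
An alternative sweep policy (maximize TPR − FAR against forgery proxy
scores) is available via `policy = "sweep"`. Score-level fusion before
thresholding was chosen over per-modality decision voting; the latter is
out of scope.

Reported rates: FAR is the percentage of forgery attempts accepted, FRR
the percentage of genuine attempts rejected, TPR = 100 − FRR, HTER =
(FAR + FRR)/2, and the EER is located on the DET curve by linear
interpolation between the sweep points straddling FAR = FRR. Rates are
carried at full precision and *truncated* (not rounded) to two decimals
for reporting — the convention under which 1.875 prints as 1.87 — via
`truncate_rate()`.

## The synthetic cohort generator

No public dataset pairs signatures with signing-time EEG, so the package
ships a generator that emulates the acquisition design end to end: 33
genuine users × 10 sessions (330 samples) and 25 forgers × 2 attempts ×
33 targets (1650 forgeries) under the default configuration. Each user's
identity is a pair of stable traits:

* a **signature template**: 2–5 strokes, each a cubic Bézier with
  user-specific control points, total duration 1.5–4 s sampled at 60 Hz (a
  typical touch-event rate). A session redraws the template with
  control-point wobble, a small affine perturbation (≈2° rotation, ≈3%
  scale) and per-point noise;
* an **EEG gamma signature**: per channel, one or two oscillators with
  user-specific frequencies in 26–40 Hz and a user-specific channel
  amplitude profile, switched on during pen strokes (raised-cosine
  envelope per stroke) on top of 1/f background noise — encoding exactly
  the stroke-locked structure the FD features measure.

Forgeries model a practiced attacker: the forged trajectory blends the
target's stroke template with the forger's residual motor distortion
scaled by `1 - signature_mimic_fidelity` (default 0.9 — shape-similar),
while the forged EEG is built from the forger's *own* gamma traits
(`eeg_mimic_fidelity = 0` by default; raising it blends in the target's
stroke-locked activity for sensitivity analyses). One master seed fans
out into per-user and per-sample sub-streams, so regeneration is exact
and adding users never perturbs existing ones.

What the generator does *not* emulate: physiological EEG (no volume
conduction, artifacts, or session drift), pen pressure or pen-up gaps,
fatigue across sessions. Passing tests on this cohort demonstrate that the
pipeline recovers identity structure of the stroke-locked-gamma form when
it is present — not field performance on real recordings.

## Experiment scales and numerical choices

The shipped experiments run at desk scale: identification uses a cohort
of 10 users × 10 sessions with five-fold cross-validation (eight training
and two test samples per user per fold), and verification attacks it with
5 forgers × 2 attempts per target, training on four folds and testing on
the held-out fold plus all forgeries. At these sizes the full recovery
suite completes in minutes on one CPU while leaving clear separation
between unimodal and fused error rates; the design counts themselves
(330/1650) are checked at full scale, where generation is cheap. Numerical
tie-breaks are all deterministic (lowest index); degenerate inputs
(constant traces, zero chords, bands above Nyquist, sub-window recordings)
raise typed errors rather than propagating NaNs; DFT agreement, Parseval,
posterior normalization and Borda conservation are enforced to 1e-9.

## Limitations

The classifier is a single-layer BLSTM trained with plain SGD — adequate
for the cohort sizes here, but no attempt is made at architecture search
or modern optimizers. Thresholds are calibrated on training-set
posteriors, which are optimistic relative to unseen-session scores; the
zero-FRR policy inherits that optimism (its FRR on held-out genuine
samples need not be zero). Cross-session normalization (z-norm/t-norm)
and template adaptation are out of scope, as are EDF/BDF ingestion and
live acquisition.
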