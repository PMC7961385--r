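---
title: "Classifying hemodynamic scenarios from radar and contact vital-sign signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hemodynamic scenarios from radar and contact vital-sign signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hemoradar)
```

## The problem

A continuous-wave (CW) Doppler radar pointed at a person's chest measures
sub-millimetre chest-wall displacement through the phase of the reflected
carrier. That displacement mixes breathing motion (0.1–0.5 Hz, millimetres)
with cardiac micro-motion (~1 Hz fundamental, tenths of a millimetre).
`hemoradar` implements an end-to-end pipeline that classifies five
*hemodynamic scenarios* — Resting, Valsalva maneuver, simulated apnea, tilt
up, and tilt down — directly from windows of such signals, without ever
computing heart rate or breathing rate explicitly. A parallel set of contact
reference channels (two ECG leads, impedance cardiogram, thoracic impedance
Z0, continuous blood pressure) supports the comparison of three input
modalities: contact, radar, and their fusion.

The package is organised as a pipeline:

1. **Synthetic cohort generator** — multi-channel recording sessions with a
   known ground truth (this is what all tests run on);
2. **Derived signals** — ellipse reconstruction of the radar I/Q
   trajectory, arctangent demodulation, displacement, respiration, heart
   sound, pulse;
3. **Preprocessing** — unified 100 Hz sampling, per-signal Butterworth
   band-passes, 20-s windows with 50% overlap, per-window [0, 1]
   normalization;
4. **Labeling** — button-press detection in a marker channel, scenario
   semantics, the ambiguous "Other" class;
5. **Balancing** — SMOTE oversampling of minority classes;
6. **Model** — branched fully-connected neural networks, one branch per
   input signal;
7. **Evaluation** — subject-blocked stratified 5-fold cross-validation with
   an internal 80/20 validation split.

## The radar model

A target at distance $x(t)$ modulates the received carrier phase by

$$\Delta\phi(t) = \frac{2\pi \cdot 2\,x(t)}{\lambda}, \qquad
  \Delta x = \frac{\Delta\phi}{2\pi}\cdot\frac{\lambda}{2},$$

with $\lambda = c/f_c \approx 12.49\,$mm at the 24 GHz carrier the package
assumes by default. The receiver digitizes in-phase and quadrature
components $I = \cos\phi$, $Q = \sin\phi$ at 2000 Hz; an ideal receiver
traces the unit circle. Real receivers add DC offsets, an I/Q amplitude
imbalance, and a quadrature phase skew, turning the circle into a translated
tilted ellipse. `ellipse_reconstruction()` fits that ellipse by direct
constrained algebraic least squares (the numerically stable Halir–Flusser
formulation of the Fitzgibbon fit — closed-form, deterministic, no
iteration) and maps it back to the centred unit circle;
`arctangent_demodulation()` then recovers the phase with the four-quadrant
arctangent and $2\pi$ unwrapping (jump threshold $\pi$). The fitted tilt is
canonicalized into $(-\pi/4, \pi/4]$ so the compensated I axis stays aligned
with the raw I axis; for realistic (mild) receiver distortions this
eliminates the quadrant ambiguity of the ellipse representation. A round
trip through synthesis → distortion → reconstruction → demodulation is exact
to machine precision on noiseless input; the test suite asserts
$<10^{-9}$ m without distortion and $<10^{-6}$ m under a 2:1 amplitude
imbalance with DC offsets.

Demodulation rejects any sample whose I/Q radius falls below $10^{-6}$
(phase is undefined near the origin).

## What the synthetic cohort emulates

The generator reproduces the *study conditions* of a clinical tilt-table
protocol, not cardiorespiratory physiology. Per scenario:

* **Resting** — 600 s of calm breathing, no events;
* **Valsalva** — the maneuver performed 3 times for 20 s each with 5 min
  recovery periods between (sessions ≈ 17 min); during each maneuver the
  breathing component is suppressed and a strain excursion (raised-cosine
  bump, default 6 mm) deforms the chest baseline, with a transient blood
  pressure elevation in the contact channel;
* **Apnea** — two breath-holds of 30–60 s (drawn per session; the hold
  duration is configuration, since protocols say only "as long as
  possible"), first at full inhale, second at full exhale (opposite
  sustained chest offsets); breathing suppressed to 4% of its amplitude;
* **TiltUp / TiltDown** — a 10 s table motion followed by 10 min of
  continued recording; the orthostatic response is modelled as a sustained
  heart-rate shift (×1.35 up, ×0.75 down), a milder breathing-rate shift,
  a signed chest-baseline step, and a sustained blood-pressure shift.

Chest displacement is additive: breathing sinusoid + cardiac pulse train +
strain + baseline terms + white noise. The cardiac component is a sharp
periodic von Mises-shaped pulse train, $\exp(\kappa(\cos\theta - 1))$ with
$\kappa = 400$, rather than a sinusoid: a smooth 1 Hz sinusoid carries no
energy in the 16–40 Hz auscultation band, so a heart-sound signal could not
be derived from it. The pulse-train harmonics extend through that band,
exactly as real valve motion transients do. ECG surrogates use the same
phase trajectory with a much sharper bump ($\kappa = 2000$) — an R-wave
spike train, not a PQRST model, because the classifier consumes waveforms
opaquely. Per-subject physiology (resting heart rate 1.0–1.3 Hz, breathing
0.20–0.30 Hz, motion amplitudes) is drawn once per subject and shared
across that subject's five sessions.

Button presses follow the protocol semantics: 0.5 s drops to 20% of
baseline at the start and end of each Valsalva maneuver and of the tilt
motion; for apnea the button is held for the whole breath-hold; resting
sessions have a flat marker. The press width and 80% drop depth are
conventions of this artifact (they must exceed the detector's 0.2 s
debounce).

What the generator does **not** emulate: hemodynamic feedback (no
baroreflex dynamics, no beat-to-beat variability), motion artifacts, radar
clutter from other body parts, electrode noise bursts, or the press-count
irregularities of real recordings. Passing tests therefore demonstrate that
the pipeline machinery is correct and that the classifier can exploit
scenario-discriminative structure; they do not certify accuracy on real
clinical recordings.

## Derived signals and preprocessing

The derived signals are documented replacements for proprietary originals
(the clinical dataset's own derivation code is closed):

* distance — the demodulated displacement, at native 2000 Hz;
* radar respiration — distance band-passed 0.1–1 Hz;
* heart sound — distance band-passed 16–40 Hz at the native rate (the band
  must be extracted before any downsampling below 80 Hz Nyquist);
* pulse — full-wave rectified heart sound, 3 Hz low-passed (a smoothed
  envelope whose peaks mark beats — an envelope rather than beat markers
  because the model consumes waveforms);
* contact respiration — thoracic impedance band-passed 0.1–1 Hz.

All filters are 4th-order Butterworth designs applied forward–backward
(zero phase), so channels stay mutually aligned for windowing — the test
suite asserts zero cross-correlation lag through the respiration band.
Numerical caveat: at 2000 Hz the 0.1 Hz lower edge sits at a normalized
frequency of $10^{-4}$ where a transfer-function biquad cascade is
numerically unstable, so `extract_respiration()` internally decimates to
~100 Hz, filters there, and interpolates back (exact for a signal band
limited to 1 Hz). Resampling to the unified 100 Hz grid uses a zero-phase
FIR anti-aliasing low-pass (Hamming-windowed, $10q+1$ taps for decimation
factor $q$, cutoff at 80% of the target Nyquist) evaluated only at retained
samples; being symmetric and applied symmetrically it introduces no group
delay. Respiration and pulse, whose content lies below 3 Hz, are computed
from the decimated traces directly — identical content at a fraction of the
cost.

Band-pass defaults after resampling: respiration-like signals 0.1–1 Hz,
everything else 0.1–20 Hz (the widest stated envelope, as used for ECG),
heart sound exempt (already band-limited). The per-signal table is a
configuration argument of `preprocess_session()`.

Windows are 20 s long with 50% overlap, anchored at t = 0, trailing
partials dropped: `count = floor((T - 20)/10) + 1`. Normalization to
[0, 1] is per window per signal — the self-contained-instance convention —
which also makes every instance scale-free; a whole-session alternative
would leak session-level statistics across the train/test split.

## Labeling and the "Other" class

`detect_presses()` finds contiguous runs below half the median baseline
lasting at least 0.2 s; runs shorter than 2 s are quick presses, longer
runs are press-and-holds. Scenario parsers turn presses into labeled
intervals: consecutive press pairs bound Valsalva maneuvers; holds bound
apnea; the first press of a tilt session starts the tilt interval, which
extends to the end of the session (the continuation is the orthostatic
response window — this convention is what makes tilt sessions nearly fully
labeled, matching the published instance distribution where the two tilt
classes hold ~19% each while Valsalva keeps only 2%). Inconsistent press
counts are flagged as errors, not silently repaired; a lenient mode infers
the dominant pairing for real recordings with irregular presses.

A window receives a class when **more than half** of its duration lies in
intervals of that class, else it is "Other" (integer code 0; the fixed map
is Other=0, Resting=1, Valsalva=2, Apnea=3, TiltUp=4, TiltDown=5). With
20-s windows on a 10-s grid and 20-s maneuvers placed off-grid, this yields
about 2 labeled windows per Valsalva maneuver. "Other" is removed before
modelling (ambiguous physiology), and the remaining five classes are
one-hot encoded. `instance_accounting()` recomputes each class's total
duration (count × 20 s) and fraction; applied to the published instance
counts of the clinical dataset it reproduces the printed durations and
percentages, which the acceptance suite asserts.

## Balancing

`smote()` implements classic SMOTE: for each minority class, synthetic
instances `x + u (x_nn − x)` with `u ~ U(0,1)` between a random member and
one of its k = 5 nearest same-class neighbours (class-internal Euclidean
k-NN; k is reduced with a warning for classes with ≤ k members), until all
classes match the majority count. Originals pass through unchanged;
synthetics are appended. The default experiment applies SMOTE to the full
dataset *before* the fold split — faithful to a design whose chance
baseline is quoted at 20% on balanced data — and a `leakage = "fold"` mode
confines SMOTE to each training fold for the stricter reading. Both are
first-class; the acceptance checks run the default.

## The branched network

One branch per input vector: each branch is `n_hidden_layers` dense layers
of `n_units` with the configured activation, inverted dropout and L1/L2
weight regularization; branch outputs are concatenated; one dense head
layer of the same width precedes a 5-unit softmax. Branch and head layers
share the width/activation/dropout hyperparameters (the architecture
diagram of the study shows a single set per network; a deeper head is a
flag away). Weights are Glorot-normal, biases zero, all seeded. Inputs are
temporal windows (2000 samples at defaults), [0, 1]-normalized FFT power
half-spectra (1000 bins — the non-redundant half of the mirrored spectrum,
phase discarded, no taper, DC bin retained since normalization makes it the
window mean), or both, which doubles the branch count: contact/radar
networks have 6 branches per data type, fusion 12.

Training minimizes categorical cross-entropy plus the regularization
penalty by minibatch gradient descent for a fixed 100 epochs — no early
stopping; the internal stratified 80/20 validation split only monitors
convergence. Optimizers: Adam, SGD, RMSprop, AdaDelta with their standard
update rules (Adam β = 0.9/0.999, ε = 1e-7; RMSprop ρ = 0.9; AdaDelta
ρ = 0.95, both accumulators, scaled by the learning rate). The searchable
grid spans 7776 combinations; `random_search()` draws without replacement
and ranks sets by mean CV accuracy. The published best fusion set uses a
learning rate (0.001) and batch size (32) outside that grid; they are
admitted through an `extended` grid flag rather than silently widening the
documented space.

**Gradient clipping.** Gradients are clipped to a global L2 norm of 1
before every optimizer step. At the top of the grid (Adam at learning rate
0.05 — the published radar configuration) training reaches ~1.0 validation
accuracy but exhibits transient divergence spikes from which it recovers
within a few epochs; with a fixed epoch budget and no early stopping, a
fold whose final epoch lands inside such a spike would be evaluated in a
meaningless state. Clipping removes the spikes without measurably changing
converged behaviour at the smaller learning rates. This is the package's
numerical-stability choice, fixed at 1 and not part of the search space.

## Evaluation design

Per-subject window sets are stacked in fixed subject order, each subject's
block contiguous and time-ordered (`stack_subjects()` rejects duplicate
ids). The default `contiguous` fold mode cuts that order into 5 consecutive
test blocks, reproducing the border-subject behaviour of block CV: at most
2 subjects per fold have windows on both sides of the split, which the
tests assert. The `subject_grouped` mode assigns whole subjects to folds —
the stricter leave-subjects-out alternative — at the price of unbalanced
fold sizes. Exact contiguity and exact stratification conflict, so achieved
per-fold class proportions are *reported* (attached to the fold object),
not enforced. Within each fold the training part is split 80/20 into
internal training and validation, stratified per class and seeded.

Metrics: categorical accuracy (argmax agreement, ties broken toward the
lowest class index — fixed and documented) and row-normalized confusion
matrices (rows without support stay zero and are flagged). Fold matrices
are averaged elementwise; the per-fold identity
`accuracy = Σ_c diag(confusion)_c · support_c / n` is asserted numerically
in the tests. A permuted-label control
(`run_experiment(..., permute_labels = TRUE)`) at 20 epochs must land
within 3 standard errors of the 0.20 chance level (standard error of the
fold mean, floored by the binomial SE of the pooled test size) — this
guards against information leaking from the fold construction itself. The
control permutes the labels of the *balanced* instance set, i.e. the
dataset the model actually trains on: permuting before SMOTE would let the
oversampler manufacture genuine label-correlated structure (minority-class
labels would be carried almost entirely by interpolated points, and
interpolatedness is learnable), which the control would then wrongly flag
as leakage.

## Problem sizes used by the checks

The test and acceptance runs use a 10-subject cohort at full-length default
sessions (~3150 s of multi-channel signal per subject, ~1940 labeled
windows, ~3000 instances after SMOTE). The radar/FFT experiment runs the
full 100-epoch budget; the contact (40 epochs) and fusion (8 epochs)
checks use reduced budgets that are already far beyond what those easier
inputs need to clear their margin; the permutation control uses 20 epochs.
These sizes are the package's scaled-down defaults for a single-CPU
reproduction; `analysis/03_train_radar_model.R` runs the same experiment
end to end.

## Degenerate inputs and edge rules

* Constant window segments normalize to all zeros (the 0/0 guard).
* `T < window_s` yields zero windows; trailing partials are dropped.
* Colinear or constant I/Q clouds are rejected by the ellipse fit with a
  diagnostic; I/Q radii below 1e-6 reject demodulation.
* An all-low marker (stuck button) has no estimable baseline and is
  rejected; a constant-high marker is a valid resting session.
* Odd Valsalva press counts and pressless tilt/apnea sessions are flagged
  errors in strict mode; lenient mode drops the trailing unpaired press.
* SMOTE on a singleton class is an error; classes with ≤ k members reduce
  k with a warning; an already-balanced dataset passes through unchanged.
* `NaN`/`Inf` training loss aborts with a diagnostic naming the epoch.

## Known limitations

* The synthetic cohort is deliberately easy relative to clinical data: the
  separability the acceptance criteria rely on is constructed, and
  accuracies on it say nothing quantitative about real recordings.
* The derived-signal definitions are documented replacements; equivalence
  with the proprietary originals cannot be asserted, only qualitative
  similarity.
* Only fully-connected branched architectures are implemented;
  convolutional and recurrent variants are out of scope.
* The MAT adapter converts through an external Python/SciPy bridge and
  requires a user-supplied channel map; it does not download anything.
* AdaDelta at the grid's learning rates moves in very small effective
  steps; it trains, but needs far more epochs than the fixed budget to be
  competitive — consistent with its role as a grid member rather than a
  recommended choice.
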