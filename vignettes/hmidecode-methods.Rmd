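---
title: "Decoding hand motor imagery from EEG: methods and design notes"
author: "hmidecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hand motor imagery from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brain-computer interfaces for prosthetic control need to tell apart
*motor imagery* tasks performed within the same hand — rest, three
grasp types, and wrist/finger flexion-extension movements (eleven
classes `A1`–`A11` in three sets) — from a handful of scalp EEG
channels. The signals of interest are the sensorimotor mu (8–12 Hz)
and beta (13–30 Hz) rhythms, which are non-stationary: their spectral
content changes within a trial. `hmidecode` implements a decoding
pipeline built around a quadratic time-frequency representation of
short EEG segments, twelve scalar time-frequency features per channel,
and a four-layer hierarchical classifier of RBF support vector
machines, together with the two evaluation protocols used in this
literature (within-subject 10-fold CV and leave-one-subject-out CV)
and a synthetic EEG generator so that the complete pipeline is testable
without access to recordings.

## Front end

Recordings are 16-channel, 10–20 montage (`Fp1 Fp2 C3 C4 Cz F3 F4 Fz
T7 T8 O1 O2 Oz P3 P4 Pz`), nominally sampled at 2048 Hz. Analyses run
on one of four electrode groups over the motor cortex: broad bilateral
G1 (11 channels), left G2, right G3, narrow bilateral G4.

Preprocessing: a zero-phase 0.5–35 Hz band-pass, then decimation to
256 Hz. The band-pass is realized as a cascade of 4th-order Butterworth
high-pass and low-pass sections, each applied forward-backward. A
single 8-pole band-pass polynomial spanning 0.5–35 Hz at 2048 Hz is
numerically unstable (its poles leave the unit circle in double
precision), while the cascade is stable at both sampling rates and has
the same nominal response; zero-phase filtering preserves waveform
timing so segment onsets are comparable across channels. Decimation
keeps every 8th sample after its own anti-alias guard (6th-order
low-pass at 80% of the target Nyquist) — redundant given the 35 Hz
band-pass, but it makes the operation safe in isolation. Note one
consequence of any realizable Butterworth: the passband is flat only to
a few times `1e-5` (for example `(10/35)^8 ≈ 4e-5` droop at 10 Hz after
forward-backward application), so "filter then decimate" and "decimate
a band-limited signal" agree to about `1e-4`, not to machine precision.

Each channel of the imagery period is segmented with a sliding window
of `W = 256` samples (1 s at 256 Hz) and overlap `O = 128`; trailing
partial windows are dropped. The first 3 s of every trial are the
visual-cue interval and are excluded from analysis — the cue period
contains no imagery and retaining it would mix visually evoked activity
into the training windows (whether the original analysis excluded it is
not stated; exclusion is the conservative choice).

An optional `artifact_hook` in `features_from_dataset()` accepts a
user-supplied recording-to-recording function after band-passing;
automatic ocular/muscular artifact removal itself is out of scope.

## The time-frequency engine

Each window `x(t)` is made analytic, `s(t) = x(t) + j H{x(t)}`, via
one-sided spectral weighting, which removes negative frequencies and
halves the interference terms of the quadratic distribution. The
Cohen-class distribution is computed in the ambiguity domain:

* instantaneous autocorrelation `K(n, k) = s(n + ⌈k/2⌉) s*(n − ⌊k/2⌋)`
  on integer lags `k = −(W−1)…(W−1)`, zero outside the window (no
  periodic extension, no interpolation). This indexing keeps `K`
  Hermitian in `k`, hence the distribution real up to FFT round-off
  (the imaginary residue is verified `< 1e-6` of the matrix norm and
  discarded);
* DFT over time to the Doppler-lag (ambiguity) plane, multiplication by
  the kernel, inverse DFT;
* DFT over the lag axis, zero-padded to `2N` points, keeping the `N`
  non-negative-frequency bins: a `W × N` surface (default `256 × 512`)
  on `[0, fs/2)` with resolution `fs/2N = 0.25` Hz.

The kernel is `ψ ≡ 1` for the Wigner-Ville distribution and
`ψ(φ, τ) = exp(−φ²τ²/γ²)` for the Choi-Williams distribution, with
Doppler `φ` in cycles/sample and lag `τ` in samples (the unitless grid
convention in which the default `γ = 0.5` was selected). Two printed
ambiguities are resolved as explicit switches: the kernel exponent's
`γ` appears in the denominator by default (smaller `γ` ⇒ stronger
suppression, consistent with choosing 0.5) with the multiplicative
variant available, and absolute feature scales may differ from other
implementations by a constant factor because grid/normalization
conventions of quadratic TFD toolboxes vary — harmless to
classification, which standardizes features anyway.

The scaling is fixed by the marginal: summed over the full frequency
axis, `Γ(t, ·) Δf = |s(t)|²` exactly, because `ψ(φ, 0) = 1` leaves the
zero-lag column untouched. Energy is conserved within 2% (the loss is
the negative-frequency residue of the analytic signal), tones localize
to within one frequency bin, and on `W = N = 32` instances the engine
matches a literal direct-summation implementation of the defining
equations to `1e-6` — these are all enforced by tests. Negative values,
inherent to quadratic distributions, are retained; magnitudes are taken
only where a feature definition says so.

The engine's FFTs run through FFTW (Armadillo's `ARMA_USE_FFTW3`),
which keeps a full 256 × 512 Choi-Williams surface under 10 ms.

## The twelve features

From each channel's surface `Γ` the package computes, per window:

| Category | Features | Meaning |
|---|---|---|
| C1 log-amplitude | TF1 `Σ log|Γ|` | overall log-energy of the surface |
| C2 amplitude | TF2 mean abs. deviation; TF3 RMS; TF4 quartile spread | amplitude dispersion |
| C3 statistical | TF5 mean; TF6 variance; TF7 skewness; TF8 kurtosis | moments of the cell distribution |
| C4 spectral | TF9 flatness; TF10 flux | uniformity / rate of change of energy |
| C5 spectral entropy | TF11 order-3 normalized Renyi entropy; TF12 energy concentration `Σ|Γ|²` | energy spread |

Numerical policies, all test-enforced:

* zero-magnitude cells are floored at `1e-12 · max|Γ|` before logs and
  geometric means, so TF1 and TF9 are always finite;
* TF2 is named "median absolute deviation" in the source literature but
  defined (and implemented) as the mean absolute deviation about the
  mean;
* the printed TF3 formula duplicates the mean; the implementation
  honours the feature's name with a true RMS, and `tf3 = "literal"`
  reproduces the printed form;
* TF4 reads the printed quartile indices as order statistics: per
  frequency bin, ranks `round((W+1)/4)` and `round(3(W+1)/4)` of the
  sorted time samples;
* TF7/TF8 on a near-constant surface (`TF6 ≤ 1e-12 · TF5²`) return 0
  with a warning instead of NaN, keeping classifiers total;
* TF11 is the third-order normalized Renyi entropy
  `−½ log2 Σ p³`, `p = Γ/ΣΓ` (the printed equation is typographically
  unreadable; order 3 is the standard concentration measure for
  quadratic TFDs, order 2 is switchable). TF1 uses the natural log
  (base unspecified in the source), TF11 base 2 as printed.

Per-channel features are concatenated channel-major in group order
(`C3:TF1 … C3:TF12, C4:TF1, …`) — whether the original analysis
concatenated or pooled channels is not stated; concatenation preserves
spatial information and is the common choice. G1 with all twelve
features gives a 132-dimensional vector per window.

## The hierarchical classifier

Six classification nodes in four layers: CN1 rest (`A1`) vs movement;
CN2 grasps vs wrist/finger; CN3 the three grasps; CN4 wrist vs finger;
CN5 the two wrist tasks; CN6 the five finger tasks. CN3 and CN6 are
one-against-one ensembles (3 and 10 binary classifiers) with majority
vote; vote ties resolve to the lowest class index — a documented,
deterministic rule. The hierarchy converts one hard 11-way decision
into a sequence of easier ones and handles the structural class
imbalance (different trial durations yield different segment counts
per class) without reweighting.

Every node is an RBF-kernel SVM, `k(u, v) = exp(−‖u−v‖²/(2σ²))`.
Features are z-scored with statistics of the training partition only
(constant features get unit scale). Hyperparameters are grid-searched —
`C ∈ 2^{−3, −1, …, 9}`, `σ ∈ 2^{−4, …, 2⁴}` by default — by stratified
inner cross-validation (5-fold by default) on the training partition
only, never on the outer test fold; the winning pair maximizes mean
inner accuracy, ties broken toward smaller `C` then larger `σ`
(weaker, smoother models). Training is bit-reproducible given (data,
grid, seed): all fold assignments derive from `split_seed()`.

## Evaluation

Per-node metrics are precision, recall, F1 and accuracy in percent.
At multiclass nodes, one-vs-rest counts are macro-averaged (unweighted
over classes — the even-handed choice under imbalance), and F1 is
recomputed from the averaged precision/recall at every aggregation
level so the harmonic-mean identity holds on every reported row. The
"overall" row is the unweighted mean over the six nodes. The cascaded
11-class end-to-end accuracy is reported alongside (a sample mis-routed
at one node can never be recovered below it).

Protocols: **SDTP** — per subject, segments are split into 10
stratified folds; node metrics are averaged over folds, then subjects.
**SITP** — leave-one-subject-out: one model per held-out subject,
trained on all others. Paired two-sided t-tests compare configurations,
paired by subject; zero-variance differences are reported as `p = 1`
(zero mean difference) or `p = 0` (documented degenerate policy).
Segments of one trial may fall into different folds under SDTP
(segmentation precedes cross-validation); `trial_grouped = TRUE`
provides the leakage-safe variant in which a trial's windows share a
fold — reported accuracies in the default mode may be optimistic in
comparison, which is why the option exists.

## The synthetic generator

`simulate_dataset()` emulates the study conditions: `n_subjects` × 11
classes × 7 trials, trial durations 10 s (rest and wrist/finger
classes), 12 s (extension-type grasp), 14 s (small-diameter and
lateral grasps), a 3 s cue interval of noise only, 16 channels at
2048 Hz by default (256 Hz is the supported shortcut for fast tests —
generation is band-limited far below either Nyquist).

Each class has a *signature*: a spatial amplitude pattern over the
eleven sensorimotor electrodes (G1) plus a center frequency in the
mu/beta range. `separability ∈ [0, 1]` blends all signatures between a
single shared template (0: classes indistinguishable by construction)
and fully distinct focus channels/frequencies (1). Rest (`A1`) carries
class components attenuated by `1 − 0.9 · separability`.
`subject_variation ∈ [0, 1]` perturbs a subject away from the shared
templates: lognormal channel-weight jitter (sd `0.5·sv`), frequency
jitter (sd `4·sv` Hz), a global gain, a noise-exponent jitter — and,
dominantly, `round(5·sv)` pairwise swaps of the spatial patterns of
movement classes, emulating inter-individual differences in cortical
topography: the same imagined task maps to different scalp patterns in
different subjects while each subject stays internally consistent.
Without the swap mechanism, weight jitter alone leaves cross-subject
transfer essentially intact, and the scalar would not span the range
its contract claims (identical subjects at 0, strong transfer loss
at 1).

Signals are amplitude-modulated tones (Gaussian burst envelopes every
~0.8 s, random phase) over 1/f background noise spectrally shaped with
a logistic roll-off above ~40 Hz, keeping more than 99% of the power
inside the analysis band. Defaults: oscillation amplitude 6 μV on the
focus channels, noise 2 μV, `separability = 0.9`,
`subject_variation = 0.3`.

What the generator does **not** emulate — and hence what passing tests
do and do not show: there is no event-related desynchronization
(imagery is modeled as band-limited power *increase*, real mu/beta
imagery suppresses power), no ocular/muscular artifacts, no volume
conduction or channel cross-correlation, no non-stationary drift.
Pipeline correctness, routing, metric arithmetic, reproducibility and
the directional SDTP/SITP behaviour transfer to real data; absolute
accuracy numbers do not.

## Problem sizes

The test suite and the acceptance script run a scaled-down study chosen
to exercise every stage at meaningful sample sizes: 6 subjects × 11
classes × 7 trials at 256 Hz, `separability = 0.95`,
`subject_variation = 0.5`, 3 analysis windows per trial (231 windows,
21 per class, per subject; 1386 in total; 132-dimensional G1 feature
vectors), with a reduced grid `C ∈ {1, 16}`, `σ ∈ {4, 8, 16}` and
3-fold inner CV. Under these conditions the subject-dependent protocol
reaches the high 90s in overall node accuracy while leave-one-subject-
out drops by roughly 25–30 points — the same qualitative ordering the
method exhibits on real recordings, produced here entirely by the
generator's subject-variation mechanism. Oracle-equivalence tests for
the engine run at `W = N = 32`, feature oracles on `8 × 16` surfaces.

## Known limitations

* The minimal EDF reader/writer supports 16-bit single-record files —
  sufficient for round-tripping this package's own exports; it is not
  a general EDF+ implementation.
* Quadratic-TFD absolute scales are convention-dependent; compare
  features only within one engine.
* The per-node grid search refits `n(n−1)/2` binary SVMs per grid
  point; with the default 63-point grid and large segment counts, SITP
  on many subjects is the slowest path (reduce the grid or use the
  `reduced` settings above for exploration).
* `simulate_dataset()` holds all trials in memory (~150 MB at the
  acceptance scale; ~10 GB for 18 subjects at 2048 Hz — write and
  stream with `write_dataset()`/`read_dataset()` at full scale).
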