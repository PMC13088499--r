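---
title: "Decoding motor imagery with state-space sequence models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with state-space sequence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

## The problem

Motor imagery (MI) — the mental rehearsal of a movement — attenuates the
sensorimotor mu (8–12 Hz) and beta (15–30 Hz) rhythms over the
contralateral motor cortex. A motor-imagery BCI turns this event-related
desynchronization (ERD) into control signals: EEG is acquired continuously,
cleaned, reduced to spectro-spatial features, classified into a small set
of imagery classes, and smoothed into continuous and binary commands for an
effector or game. `mibci` implements that full chain, with a synthetic-EEG
generator in place of hardware so every stage is testable and seeded.

This vignette explains the models and the decisions behind the defaults.
It states no empirical result beyond what the package's test suite and
acceptance script themselves compute.

## The synthetic-EEG generator

`generate_recording()` emulates a cue-paradigm session: per trial a 3 s
break, a 1 s arrow cue, and a 3 s imagery/rest period, with class order
randomized by the seed. Task onset is defined as cue offset (imagery starts
when the cue disappears), so task markers sit 1 s after their cue markers
and consecutive task onsets are 7 s apart.

The signal model per channel is

* 1/f background noise (spectral exponent 1 by default, RMS 8 µV),
* sinusoidal mu (10 Hz) and beta (20 Hz) components whose amplitude is
  multiplied by `1 - d` during a task of class `c` at channels configured
  in `erd_depth[[c]]` — band power therefore scales as `(1 - d)^2`, which
  is what the ERD validation helpers (`band_power()`, `erds()`) measure,
* stereotyped artifacts: frontal-weighted biphasic blink transients
  (~300 ms, 150 µV at the frontal pole, decaying with 2-D electrode
  distance), temporal-weighted >30 Hz muscle bursts (~500 ms, 5× the
  background RMS), and a common 50 Hz line component.

Two generator choices deserve justification:

* **Rhythm topography.** The default amplitudes give the sensorimotor
  strip a prominent mu/beta rhythm (10/5 µV against 4/2 µV elsewhere over
  the 8 µV broadband floor). This is the physiological regime the method
  targets: in real sensorimotor EEG the mu rhythm is a visible spectral
  peak at central electrodes, and single-condition ERD is evident in
  trial-averaged spectrograms. With a rhythm buried in the 1/f floor, ERD
  of any depth would be undetectable by any decoder, so a "strongly
  separated" three-class condition — the regime the recovery benchmark is
  defined in — requires a visible rhythm. The choice was made once, on
  physiological grounds, and is the package-wide default.
* **ERD layout.** `default_erd_depth(0.6)` puts the peak attenuation at
  the focal contralateral electrode (C4 for left-hand, C3 for right-hand
  imagery) with half-depth spread to its frontocentral/centroparietal
  neighbours, matching the spatially extended ERD seen in scalp
  topographies; rest carries no modulation.

What the generator deliberately does **not** model: volume-conduction
forward physics, non-stationary drifts, inter-session covariance shifts,
eye-tracking/EMG side channels, and realistic artifact morphology beyond
the two stereotypes. Passing tests on synthetic data therefore demonstrate
pipeline correctness (bookkeeping, equivalences, recoverability of a
planted effect), not clinical-grade decoding performance on real patients.

## Preprocessing

**Band-pass.** An IIR Chebyshev type 2 filter of total order 16 with
stopband edges 4–36 Hz. The design is bought from `signal::cheby2` and
converted in-package to cascaded second-order sections (r-signal offers no
zpk-to-SOS path); direct-form II transposed sections carry per-section
state so that chunked streaming output equals batch output to machine
precision — the property the online pipeline rests on. The stopband
attenuation is the one free design knob (family, order, band being fixed);
it was calibrated once by grid search over 20–60 dB against the chain's
500 ms group-delay design goal and frozen at 60 dB, the in-range value
whose mean 8–30 Hz delay comes closest to that goal. The realized delay of
this design is much smaller (~64 ms mean over 8–30 Hz, reported by the
acceptance script); an IIR of this order and bandwidth cannot exhibit a
half-second passband delay, so the design goal is unattainable within the
stated family — the calibration takes the closest attainable point rather
than silently changing family or order. At 60 dB the response at 50 Hz is
below −60 dB, which is why no separate notch filter is used.

**ASR.** Artifact subspace reconstruction is fitted on ≥30 s of clean
calibration data *after* band-pass filtering (where it operates in the
chain): component directions are the eigenvectors of the calibration
covariance (Euclidean average of 0.5 s windowed covariances), and each
component's RMS over sliding windows gets a rejection threshold of
`mean + 3 SD`. The 3-SD multiplier is far more aggressive than the 10–20
common in the ASR literature; it is kept as the configured default and
exposed as a parameter. Because the directions diagonalize the calibration
covariance, reconstruction of a flagged component from the non-flagged
subspace reduces exactly to removing that component's contribution in the
window. At most a fraction 0.4 of components is reconstructed per window
(worst offenders first); windows exceeding the cap are flagged in the
quality report, never zeroed, since the online pipeline must emit
continuous output.

**Referencing and epoching.** The common average reference is applied
after ASR (ASR needs full-rank input). Epochs are `[0, 3)` s from task
onset; baseline correction subtracts the per-trial, per-channel mean over
`[-1, 0)` s before *cue* onset — a quiet break-period interval — which
requires the continuous recording, so `baseline_correct()` takes it as an
argument. Normalization is a per-(session, channel) z-score with stored
statistics, reapplied verbatim to online windows.

**CSP after CAR.** CAR makes every spatial covariance exactly singular
(the all-ones direction is annihilated), while CSP is specified without
regularization — strictly incompatible requirements. `fit_csp()` therefore
errors on rank deficiency by default but offers
`rank_deficient = "subspace"`, whitening within the non-degenerate
principal subspace (eigenvalues above `1e-10` of the maximum). This is the
standard remedy after re-referencing, changes nothing for full-rank data,
and is what `train_decoder()` uses.

## Features

Single-trial Morlet power uses L1-normalized complex wavelets (2 cycles
per frequency, 8–30 Hz in 2 Hz steps, 12 bins) so that a matched sinusoid
of amplitude `a` yields power `a²/4` at every analysis frequency; the time
axis is decimated by 3. "Keeping every third output" is read as temporal
decimation — the standard reading for time-frequency features. CSP is
one-vs-rest with the top and bottom generalized eigenvector per class
(3 × 2 = 6 filters), fitted on training windows only and serialized with
the checkpoint; its log-variances are tiled along the decimated time axis
and stacked under the flattened Morlet planes (24 × 12 + 6 = 294 feature
channels). Windows are 1 s, four per 3 s trial (stride 2/3 s), and the
80/20 split is stratified at the source-trial level so windows from one
trial never straddle the split.

## The S4D classifier

Each S4D kernel is a diagonal complex state-space system discretized by
zero-order hold: `Ā = exp(dt·A)`, `B̄ = (Ā − 1) A⁻¹ B`, with impulse
response `K[l] = 2 Re(Σ_n C_n B̄_n Ā_n^l)` over `state_dim/2` modes
(conjugate symmetry supplies the factor 2). Initialization follows the
S4D-Lin scheme: `A_n = −1/2 + iπn`, `B = 1`, complex-normal `C`, `dt`
log-uniform in `[1e−3, 1e−1]` per channel. `Re(A) < 0` and `dt > 0` are
maintained through log-reparameterization, so `|Ā| < 1` — stability — holds
by construction throughout training. The kernel is evaluated as a
Vandermonde-structured product and applied by FFT convolution (zero-padded
to 2L, truncated to L, i.e. causal linear convolution); the test suite
verifies it against a literal step-by-step recurrence on random parameter
draws to 1e−5 relative error, which is the module's core oracle.

A block is: pre-layer-norm over channels, forward and time-reversed S4D
convolutions (concatenated — the bidirectional reading), a per-channel
`D` skip term, GELU, dropout (0.4 in the full configuration), a pointwise
output convolution to twice the width, a gated linear unit back to width,
and a residual connection. Three blocks of hidden width 256 form the full
model; temporal mean pooling and a linear head produce three-class
softmax probabilities.

Training is plain Adam on cross-entropy with an `ssm` parameter group
(`A`, `dt`) at one tenth the learning rate and no weight decay — standard
S4 practice — with early stopping on validation accuracy and
best-checkpoint restoration. All gradients, including those through the
ZOH discretization into `A`, `dt`, `B`, `C`, are derived analytically and
checked against central finite differences in the suite. Input features
are standardized per feature channel with statistics estimated on the
training set and stored in the checkpoint (applied inside every forward
pass, so the online path inherits them automatically); without this the
raw power/log-variance scales differ by orders of magnitude and
optimization stalls. Monte-Carlo dropout keeps dropout active at inference
over `n_passes` stochastic passes and reports the per-class mean, its SD,
and the predictive entropy of the mean — both uncertainty statistics are
returned since neither is canonical.

The checkpoint stores configuration, parameters, classes, feature-scaling
and a plain-text feature-specification hash; the online pipeline refuses
to start when its feature configuration hashes differently.

## The online runtime

R is single-threaded, so "independent modules running in parallel" is
realized as cooperative stages — acquisition (replay), preprocessing,
classification, transfer — connected by order-preserving bounded queues
that drop the *oldest* entry on overflow and count drops. The contract
(ordering, non-blocking handoff, drop-oldest, fully stamped lineages) is
what the tests pin down; a threaded or networked transport can implement
the same contract behind the same interface. Preprocessing carries filter
and ASR state across chunks and emits 1 s windows at a 0.5 s stride;
`decode_batch()` applies the identical stateful operators to the whole
recording in one call, which is why chunked replay reproduces batch
probabilities to numerical identity (the headline offline/online
equivalence, asserted at 1e−5).

The transfer function averages the last `buffer_len = 10` probability
vectors; the argmax class is emitted when its mean clears its threshold
(0.5 by default), otherwise an explicit neutral token; argmax ties break
toward the earliest configured class. Binary accumulators rise by 0.25 per
mapped decision and decay by 0.25 otherwise, clamped to [0, 1], firing for
one tick on reaching 1. Buffer length, thresholds and rates are
runtime-adjustable configuration, not measured constants. Latency
summaries use nearest-rank percentiles so printed values are exactly
reproducible on synthetic logs, and `compute_itr()` is the Wolpaw rate
with the `0·log 0 = 0` convention.

## The training game

The QuickTime evaluator is deterministic: the bar starts at 0, gains
`fill_rate` per matching decision, loses `decay_rate` otherwise (clamped
at 0 — it cannot go negative), and succeeds the first tick it reaches the
threshold within the 3 s window. Defaults (fill 1, decay 0.5, threshold 5,
0.1 s ticks) are package choices sized so a ~55%-accurate per-tick decoder
succeeds on a comfortable majority of trials; success is counted strictly
as successes/trials.

## Numerical conventions and problem sizes

Time is in seconds, intervals are half-open `[t0, t1)`, sample indices are
0-based in window arithmetic. Zero-variance CSP projections floor at
`log(1e−12)`; normalization SDs floor at `1e−12` with a flag; layer-norm
uses a `1e−5` variance epsilon. The test suite runs the recovery benchmark
at the study condition (three classes, 40 trials per class, ERD depth 0.6)
with a reduced model (hidden 32, one layer, state 32) and a 120 s
recording for the streaming equivalence — sizes chosen so the full suite
completes on a laptop-class single core in minutes while still exercising
every stage at realistic dimensionality.

## Known limitations

* The 500 ms group-delay design goal for the stated filter family is
  unattainable (see above); the shipped filter is the calibrated closest
  point and its true delay is reported, not asserted.
* The generator's artifacts are stereotypes; ASR behavior on real
  concurrent artifact mixtures is not covered by these tests.
* Early stopping monitors the same held-out split used for test
  accuracy (the single-split protocol of the study design); for unbiased
  model selection a three-way split would be needed.
* EDF I/O is minimal (16-bit, 1 s records, sidecar JSON markers); XDF and
  live LSL/Bluetooth acquisition are out of scope, replaced by the replay
  stream behind the same chunk interface.
* Riemannian transfer learning across users/sessions is not implemented.
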