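---
title: "Methods: the hybrid EEG-fNIRS three-class analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid EEG-fNIRS three-class analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the analysis it implements:
the signal model, the classification machinery, the sensor-selection
searches, the synthetic-participant generator that makes all of it testable,
and the numerical and design decisions taken where more than one reasonable
choice existed.

## The problem

A hybrid brain-computer interface records EEG and functional near-infrared
spectroscopy (fNIRS) simultaneously while the user performs one of three
mental tasks: mental arithmetic (MA), right-hand motor imagery (MI), or
nothing at all (idle state, IS). The two modalities are complementary. Motor
imagery suppresses the mu (~10 Hz) and beta (~20 Hz) sensorimotor rhythms —
event-related desynchronization (ERD) — which EEG sees with millisecond
resolution but fNIRS does not. Mental arithmetic drives a slow hemodynamic
response over the prefrontal cortex (oxygenated hemoglobin up, deoxygenated
down, peaking several seconds after task onset) which fNIRS sees directly.
A classifier that fuses both should discriminate all three states better
than either modality alone, and the practical question is how few sensors —
EEG electrodes and fNIRS source-detector (SD) pairs — suffice to stay above
the conventional 70% effective-BCI accuracy threshold.

## Preprocessing

EEG is downsampled to 200 Hz (anti-aliased with an 8th-order zero-phase
Butterworth lowpass at 80% of the target Nyquist, then decimated) and
bandpass-filtered to 1-50 Hz. fNIRS optical densities at 780, 805 and 830 nm
are converted per channel and time point to concentration changes of
deoxy- and oxy-hemoglobin through the fixed modified Beer-Lambert law matrix
(units mM·cm):

$$\begin{pmatrix}\Delta HbR\\ \Delta HbO\end{pmatrix} =
\begin{pmatrix} 1.8545 & -0.2394 & -1.0947\\
               -1.4887 & \phantom{-}0.5970 & \phantom{-}1.4847\end{pmatrix}
\begin{pmatrix}\Delta OD_{780}\\ \Delta OD_{805}\\ \Delta OD_{830}\end{pmatrix}$$

and then bandpass-filtered to 0.01-0.09 Hz, the band that keeps the
task-locked hemodynamic response while rejecting drift, Mayer waves
(~0.1 Hz), respiration and cardiac pulsation.

Filtering happens on the continuous recordings, before epoching, to avoid
edge artifacts inside trials. EEG epochs cover 0-10 s after task onset;
fNIRS epochs cover -1 to 15 s (the hemodynamic response lags by seconds) and
are baseline-corrected by subtracting the per-channel mean over [-1, 0) s.

Three numerical decisions matter here:

* **"6th-order zero-phase"** is read as *design order 6, apply
  forward-backward* (the common EEG-toolbox convention), so the effective
  magnitude response is the square of a 6th-order Butterworth and the net
  phase is zero. The order is a `filter_spec()` argument for anyone who
  prefers the other reading.
* **Second-order sections.** The 0.01-0.09 Hz band at a 10 Hz sampling rate
  puts all twelve poles of the bandpass very close to `z = 1`; the flat
  transfer-function polynomial is numerically unstable there (its impulse
  response diverges), so the design is carried out analytically in
  zero-pole-gain form — Butterworth prototype poles, bandpass transform,
  bilinear transform — and applied as cascaded biquads. Records are
  reflection-padded by roughly three time constants of the slowest band edge
  before the forward-backward pass.
* **Half-open epoch windows** `[start, end)`: a 10 s epoch at 200 Hz is
  exactly 2000 samples, a 16 s fNIRS epoch at 10 Hz exactly 160.

## Features

**EEG: filter-bank CSP.** Each epoch is bandpassed into theta (4-8 Hz),
alpha (8-13 Hz) and beta (13-30 Hz). Per band and class pair, common spatial
patterns solve the generalized eigenproblem $C_A w = \lambda (C_A + C_B) w$
where $C_A, C_B$ are class-average covariance matrices; the whitening
construction keeps the eigenvalues in $[0,1]$ and the filters jointly
diagonalize both class covariances. Per-trial covariances are
trace-normalized before averaging (standard CSP practice; scale differences
between trials should not dominate the average), but the log-variance
features use the raw per-trial covariance: the spatial filters are applied
and the natural log of the per-component population variance (denominator
N) is taken. Component count is `k = min(n, 6)` for `n` channels; when
`n > 6` the first and last three components by eigenvalue are kept (the
extreme eigenvalues carry the class contrast). Ties in the eigenvalue
ordering are resolved by the deterministic ordering of the symmetric
eigensolver, and each filter's sign is fixed by making its
largest-magnitude coefficient positive, so refitting is bit-reproducible.
With three bands the feature count is `3k` per trial; variance floors at
`1e-30` guard degenerate constant projections. The choice of natural log
and of the population variance are classifier-irrelevant (monotone
transform, constant offset) and simply documented.

**fNIRS: temporal window means.** For every trial, channel and chromophore,
the mean amplitude over 0-5, 5-10 and 10-15 s — 96 features for 16 channels.
Multiple windows let the classifier see the rise, plateau and decay of the
response rather than a single average.

The per-trial band covariances and fNIRS window means involve no
cross-trial fitting, so `prepare_trials()` computes them once per
participant; all fold-dependent fitting (CSP averages, classifiers) happens
inside the cross-validation loop on training trials only. A bitwise test
corrupts held-out trials and asserts the fitted models are identical.

## Classification

The three-class problem is decomposed one-versus-one (MA-MI, MA-IS, MI-IS)
because CSP is inherently binary. Per pair:

* one shrinkage-LDA (sLDA) classifier on the EEG features and one on the
  fNIRS features. sLDA uses the analytic Ledoit-Wolf estimate
  $\hat\Sigma = (1-\gamma) S + \gamma \nu I$, $\nu = \mathrm{tr}(S)/p$, with
  $\gamma$ the closed-form optimum clipped to $[0,1]$, on pooled
  class-centered samples; weights $w = \hat\Sigma^{-1}(\mu_1 - \mu_0)$ and
  bias $b = -w\cdot(\mu_0+\mu_1)/2$. Shrinkage is what keeps the 96-dim
  fNIRS problem solvable from ~50 training trials.
* a meta-classifier (also sLDA, two inputs) on the *decision values* of the
  two base classifiers. The base outputs used for meta-training are
  out-of-fold predictions from an internal 5-fold stratified split of the
  training trials (stacking), because in-sample decision values are
  optimistically large and would mis-calibrate the meta weights; the base
  models are then refit on all training trials. Decision values rather than
  hard labels were chosen because margins carry the information the fusion
  needs; the internal split is assigned round-robin within class in index
  order — deterministic, no RNG, so refits are bit-identical. The CSP
  filters are fit once per training fold (not per internal stacking fold),
  the usual practice for feature extractors in stacking.

Each pair's meta decision casts one vote; the majority wins. A 1-1-1
cyclic tie goes to the class whose winning vote has the largest absolute
decision value (deterministic; ties of that kind are rare but must not
depend on class ordering).

Evaluation is a 10x10-fold stratified cross-validation: per repeat, a fresh
seeded stratified partition; accuracy is averaged over folds, then over
repeats, with the standard deviation reported across repeat means.
Stratification keeps the three classes balanced in every fold at 90 trials.
`eeg_only` and `nirs_only` modes vote on the base decision values of the
corresponding modality, bypassing the meta stage.

## Sensor selection

EEG channels are selected under the MI-vs-IS criterion (the pair the EEG
carries), fNIRS SD-pair arrangements under MA-vs-IS (the pair the
hemodynamics carry); both reuse the same leakage-free CV engine.

* `sbs_channels()`: greedy sequential backward selection from all 11
  channels down to 2 (CSP needs two), removing at each size the channel
  whose removal maximizes the criterion accuracy and recording the full
  trace.
* `exhaustive_pairs()`: all C(n,2) two-channel combinations, ranked by the
  cross-participant mean — the oracle the greedy search is compared against.
* `common_subset()`: the size-m subset maximizing the mean accuracy across
  participants, for a cohort-level common montage.
* `sd_pair_search()`: evaluates the channel sets induced by lattice
  arrangements of 1-6 SD pairs, flags arrangements under the 70% threshold
  and reports the best per pair count. The shipped arrangement table
  (`inst/extdata/sd_arrangements_synthetic.yaml`) is a synthetic stand-in
  for real optode geometry: two lattice pairs induce four channels, with
  left-DLPFC (channels 5, 10, 11, 16) and right-DLPFC (1, 6, 7, 12) blocks
  among the two-pair options.

## The synthetic-participant generator

`generate_participant()` emulates the statistical structure the analysis
relies on, with 30 trials per class, 10 s tasks, 16-18 s uniform random
rests, 11 central EEG channels (1000 Hz by default, so the downsampling
stage is exercised; fNIRS at 10 Hz, a typical continuous-wave instrument
rate):

* **EEG**: 1/f background noise (spectrally shaped white noise, sd
  `noise_sd_eeg` = 10 uV) plus mu (10 Hz, 8 uV) and beta (20 Hz, 4 uV)
  rhythms. During MI task windows the rhythm amplitude is attenuated by
  `erd_depth` times a per-channel topography peaking contralaterally
  (C3/CP3 for right-hand imagery), with 0.5 s raised-cosine ramps. Mu and
  beta topographies can differ (`erd_weights`, `erd_weights_beta`), as they
  do in real recordings.
* **fNIRS**: per-trial hemodynamic responses for MA — a double-gamma kernel
  (peak 6 s, undershoot 16 s, ratio 1/6) convolved with the 10 s task
  boxcar and peak-normalized, so `hrf_amp_hbo` (+0.04 mM·cm) and
  `hrf_amp_hbr` (-0.015) are exact peak amplitudes — weighted by a
  prefrontal topography peaking over the left DLPFC. The planted ΔHbR/ΔHbO
  are mapped to three optical densities through the Moore-Penrose right
  inverse of the Beer-Lambert matrix, so `od_to_hemoglobin()` recovers them
  *exactly* (tested to 1e-9 relative) when noise is off. Physiological OD
  noise adds slow drift, an in-band low-frequency oscillation, a Mayer
  wave, respiration, cardiac pulsation and white noise, scaled by
  `noise_sd_od`.
* **Variability**: real accuracies are far from deterministic, and the
  generator owes most of its realism to two variability mechanisms. Slow
  band-power envelopes `exp(av * z(t))` (knots every 2 s,
  `av = amp_variability` = 0.5) are drawn *per channel and per band*,
  mixed with a global arousal-like component (`env_global_share` = 0.25).
  Independent per-channel-and-band fluctuation is essential: if the
  envelope were common, CSP could cancel it through any uninformative
  reference channel (or a reference band within a channel) and every
  configuration would classify at ceiling — a structural artifact, not a
  property of real data, where band-power dynamics are dominated by local
  cortical excitability. Second, the per-trial effect strength (ERD depth,
  HRF amplitude) is jittered by `U(1-av, 1+av)`, shared across channels as
  a single physiological state per trial.
* **IS trials carry no planted effect**, and MA plants nothing in EEG, MI
  nothing in fNIRS — the complementarity the hybrid design depends on.

What the generator does *not* emulate: volume conduction and realistic
spatial covariance of EEG noise, ocular/muscle artifacts, motion artifacts,
superficial (scalp) hemodynamics, inter-channel correlated fNIRS noise, or
non-stationary learning/fatigue effects across a session. Tests passing on
synthetic cohorts therefore validate the *pipeline* — its math, its
leakage-freedom, its selection logic — not field performance on recorded
data.

## Calibration of the default conditions

The defaults were fixed once so that default cohorts behave like realistic
participants rather than noise-free idealizations: two-channel MI-vs-IS in
the low-to-mid 90s, the compact hybrid in the 80s-90s with clear
between-participant spread, EEG-only three-class in the 60s-70s (the MA-IS
vote is uninformative in EEG), and chance-level behavior (33.3%) when all
effects are zeroed. `study_config()` additionally jitters each simulated
participant's effect sizes by ±25% to mimic between-subject variability.

## Channel-recovery experiment design

The acceptance suite asserts that the selection searches recover planted
channels in at least 9 of 10 cohorts. Identifiability of a specific *pair*
imposes three conditions, each visible in the test configuration. The two
planted channels must carry complementary information (a mu-band effect on
C3 and a beta-band effect on Cz): if both carried the same effect, the
shared per-trial effect jitter makes the second channel largely redundant
and pairs of one informative and one noise channel tie with the planted
pair. The criterion accuracy must not saturate — at 100% every pair
containing one informative channel ties and the ranking degenerates — so
the planted depth is moderate (0.3 with matched 8 uV rhythm amplitudes).
And the envelope variability is kept at 0.3 with no global component, so
spurious label correlations of noise channels at 60 trials stay below the
planted advantage. The criterion itself is evaluated with a 5-fold, 6-repeat
CV.

## Statistical module

`fisher_ci()` implements $\tanh(\mathrm{arctanh}(r) \pm z_{0.95}/\sqrt{n-3})$
and `wilcoxon_effect_size()` implements $Z/\sqrt{N}$ — both in the standard
square-root forms, which reproduce the published example intervals
(r = 0.944, n = 27 gives 0.88-0.97 at two decimals) where typographically
degraded variants do not. `compare_configurations()` delegates the omnibus
test to `stats::friedman.test` and the post-hocs to `stats::wilcox.test`
(normal approximation), applies Benjamini-Hochberg FDR correction via
`stats::p.adjust`, and computes effect sizes from its own tie-corrected
signed-rank Z (verified to match the wilcox.test p-value exactly);
N is taken as the total observations entering each pairwise comparison,
i.e. twice the participant count. A fully tied table yields an omnibus
statistic of 0 and p = 1.

## Problem sizes in the test suite

The full study conditions are 30 trials per class at 1000 Hz EEG. The test
suite generates its cohorts at the native 200 Hz pipeline rate (the
1000-to-200 Hz downsampling stage has dedicated tests of its own) and uses
reduced CV repeat counts for the selection criteria; the chance-level and
effective-BCI checks run the full 90-trial cohorts. The toy fixtures used
for classifier mechanics are 20-60 trial epoch sets built directly in the
test helpers.

## Known limitations

* The dataset container is a directory of RDS payloads plus JSON metadata,
  not an HDF5 file; EDF and SNIRF import adapters are declared but not
  implemented.
* The generator's fNIRS noise is independent across channels, which makes
  spatial fNIRS selection somewhat easier than on real data where
  systemic physiology correlates channels.
* `exhaustive_pairs()` is quadratic in channels and each cell is a full CV;
  it is meant for the 11-channel montage, not high-density caps.
* The analysis is strictly offline; no online/asynchronous decoding, and no
  information-transfer-rate computation.
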