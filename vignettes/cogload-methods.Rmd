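---
title: "Methods: simulating and analyzing cognitive load from single-channel frontal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing cognitive load from single-channel frontal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem

Repeated practice of a demanding psychomotor task — the motivating case is
medical students training on a laparoscopic surgery simulator — improves
behavioral performance while the working-memory demand ("cognitive load")
of the task falls. Frontal EEG carries usable correlates of that load:
theta (4–7 Hz) and delta (0.5–4 Hz) band power both increase with load,
and a linear combination of wavelet-packet features of a single forehead
channel, trained to separate high- from low-load conditions, tracks it
more sensitively still.

`cogload` packages that whole analysis as tested, reusable code. Because
no public recording of this kind of study exists, the package also
contains a first-class synthetic-cohort generator that emulates the
statistical structure the analysis assumes, so every stage — feature
extraction, biomarker derivation, and the trial-level statistics — can be
exercised and validated end to end under known ground truth.

## The synthetic cohort generator

A `load_scenario()` fixes one experiment: `n_participants` people, three
trials each, under one of three scheduling regimes:

* `same_session` — three back-to-back trials; latent load follows a
  linearly decaying practice curve `load_start - (trial-1) *
  load_decay_per_trial`.
* `next_day` — a follow-up session after performance has plateaued; load
  is frozen at the final level of the practice curve (the ceiling-effect
  interpretation of a next-day session).
* `daily` — one trial per day. The load trajectory uses the same decaying
  form (the `scenario_daily()` preset sets the decay to zero), and
  `offline_gain_per_trial` can add behavioral improvement that is *not*
  mediated by load. This decoupling is deliberate: overnight-consolidation
  ("offline") gains improve performance through motor-learning circuits
  without the frontal working-memory signature, and no generator whose
  behavior is a pure function of latent load could produce that
  dissociation.

Each participant gets a Gaussian load offset (SD `between_subject_sd`,
default 0.05), and the trajectory is clipped to [0, 1].

**EEG.** One trial's recording is a sum of frequency-domain band-limited
Gaussian noise components on a pink (1/f-amplitude) background, plus white
sensor noise, at 500 Hz on a single referenced forehead derivation
("Fp1-Fpz"). Delta and theta RMS amplitudes are affine *increasing* in
load (defaults: delta 5·(1+1.2·load) µV, theta 4·(1+1.5·load) µV — the
coupling direction both bands show with working-memory load); alpha
(8–12 Hz, 4 µV) and beta (13–30 Hz, 2 µV) are load-independent; the pink
background is 8 µV RMS and sensor noise 2 µV. Components are synthesized
with exact target RMS, so tests can compare measured band power against
the closed form. The generator makes no attempt to emulate eye blinks,
EMG, electrode impedance drift, or non-stationarity within a trial;
passing tests therefore validate the *analysis machinery*, not robustness
to real-world artifacts.

**Behavior.** Accuracy and economy of movement (percent) are affine
decreasing in load (95 − 45·load and 85 − 50·load), task time affine
increasing (110 + 100·load seconds), each with Gaussian noise (default SD
4 points; 2.5× that, in seconds, for time) and clipping to the legal
range. The anchors were chosen once to put simulated scores and per-trial
changes in the ranges a beginner simulator task produces, with per-trial
standardized effects of the same order as the large practice effects the
design targets; they are configurable but are not tuned per analysis.

**Trial length.** The default `trial_duration_s = 144` matches the mean
task-completion time the analysis is built around. The replication
ensembles in the test-suite and acceptance script use 20-s trials: a
per-trial mean over 20 one-second epochs already has a standard error far
below the simulated effect sizes, and the ensemble sizes (100 seeds ×
three designs) are chosen so the whole battery stays a desk-scale
computation. These sizes are stated here as the package's own study-size
choices.

**Determinism.** Every random draw is seeded through a deterministic
integer mix of the scenario seed with the participant, trial, experiment
and component identity, so cohorts are bit-reproducible and a
participant's load offset persists across experiments while their two
sessions get independent noise realizations.

## The wavelet-packet feature bank

The packet tree is generated by a conjugate quadrature pair: the low-pass
("averages") and high-pass ("differences") convolution–decimation
operators applied recursively with periodic boundary handling, giving
2^d nodes at depth d, indexed by (scale, frequency) in natural (Paley)
order. The default filter is Daubechies with four vanishing moments
(`db4`, 8 taps); Haar is retained because its transforms are hand
checkable, and every pair must pass the orthonormal quadrature identity
to 1e−10 at construction. Periodic extension keeps the transform exactly
orthogonal, so Parseval bookkeeping is exact and tested against an
explicit dense-matrix construction of the basis.

Choices the tree leaves open, fixed here once:

* **Depth 6 on 512-sample epochs.** One-second epochs at 500 Hz are
  symmetrically zero-padded to 512; depth 6 yields 2+4+…+64 = 126
  candidate nodes of ≈3.9 Hz leaf bandwidth, the smallest depth with at
  least 121 candidates.
* **Pruning by robust energy ranking.** Candidate nodes are ranked by the
  *median* across calibration epochs of their per-coefficient energy and
  the top k = 121 are retained ("brain-activity features", BAFs), with a
  deterministic (scale, frequency) tie-break. The median is the robust
  location statistic; it ignores rare high-energy epochs.
* **Feature nonlinearity.** A feature is `log(1 + RMS)` of the node's
  coefficients within the epoch: non-negative, scale-compressing, and
  monotone in amplitude.
* **Best basis.** The Coifman–Wickerhauser bottom-up dynamic program over
  an additive information cost (Shannon entropy of normalized coefficient
  energies, or log-energy) returns the minimum-cost disjoint cover; since
  the root and all uniform depths are candidates, the selected cost can
  never exceed theirs, which the tests verify exhaustively.

## The band-power pipeline

Per one-second epoch, Welch's method with 0.5-s Hann segments and 50%
overlap estimates the PSD; the per-Hz density is averaged over each band
(delta 0.5–4, theta 4–7, alpha 8–12, beta 13–30, gamma 30–50 Hz — the
alpha/beta/gamma edges are the conventional ones, bounded by the 1–50 Hz
analysis range) and expressed as dB relative to a fixed 1 µV²/Hz
reference. EEG power is not a power in watts, so only differences and
correlations of these dB values carry meaning and the reference cancels.
Two numerical details: the recording-wide mean is removed once instead of
per-segment demeaning (per-segment demeaning bites into the lowest
in-band bin through the window main lobe and biases delta by over 1 dB),
and zero-variance epochs are flagged and excluded from trial means rather
than being emitted as −∞.

With 0.5-s segments the frequency resolution is 2 Hz, so a band edge at
7 Hz splits a bin; integrated band power from this pipeline is therefore
compared against closed forms via a full-length periodogram oracle in the
tests, while the Welch pipeline itself is validated on tone-concentration
and gain-shift properties that are exact under its own binning.

## The load biomarker

The biomarker is Fisher's linear discriminant on the pooled per-second
feature rows of a labeled calibration corpus (high-load segments drawn at
latent load ≥ 0.8, low-load ≤ 0.2, 50 segments of 10 s per class by
default): weights solve `(Sw + λI) w = μ_high − μ_low` with the pooled
within-class covariance `Sw` and a small ridge `λ = 1e−6 · trace(Sw)/p`
guarding near-singularity. The raw score is `Ψ(w·x + b)` with a linear Ψ
by default (a logistic Ψ is available), and the 1–100 display scale is an
affine map sending the 1st/99th percentiles of the calibration raw scores
to 1/100, clipped — percentile anchors rather than min/max so one outlier
segment cannot compress the scale. The proprietary weight vector of the
original commercial biomarker is not public; this package re-derives an
*analogous* biomarker by the same stated procedure on its own calibration
corpus, so only sign- and validity-level properties (cross-validated AUC,
monotonicity in latent load, direction of trial effects), never published
coefficient values, are reproducible.

## The statistical battery

Per trial, every dependent variable is the temporal mean over the trial's
one-second epochs, joined with the behavioral scores: accuracy, economy,
time, the normalized biomarker, and each band power.

* **Gating.** Shapiro–Wilk per trial group plus Levene's test (center =
  mean) across groups, each at two-tailed α = 0.05; any rejection routes
  the variable to the exact paired Wilcoxon tests instead of the mixed
  model. A constant group leaves Shapiro undefined and routes to Wilcoxon
  with a warning. Note the arithmetic of this rule: with four independent
  gates at α = 0.05, perfectly normal data keep the mixed model with
  probability ≈ 0.95⁴ ≈ 0.81, and the test suite asserts that band.
* **Mixed model.** `dv ~ 1 + trial2 + trial3 + (1 | participant)` by
  REML (lme4), with trial-1-referenced indicator variables, so both trial
  contrasts are read directly from the fit without multiplicity
  correction. Inference is Wald (z, two-sided normal p, 95% CI) to match
  the z-column convention of the motivating analysis. A random intercept
  per participant is the maximal stably estimable structure with three
  observations per subject; a random slope on dummy-coded trial is not
  identifiable here. Effect sizes are a Cohen's-d analog: coefficient
  divided by `sqrt(σ²_subject + σ²_residual)`, the SD of a single
  observation.
* **Exact Wilcoxon.** Signed ranks of the nonzero paired differences; W
  is the smaller rank sum. For n ≤ 25 the two-sided p comes from the
  exact null distribution computed by dynamic programming over the
  (possibly tied, half-integer) ranks; beyond that a normal approximation
  with continuity and tie corrections is used. The exact path is verified
  against full 2ⁿ sign enumeration.
* **Repeated-measures correlation.** The ANCOVA formulation `y ~ subject
  + x`: common within-subject slope, `r_rm = sign(slope)·sqrt(SS_x /
  (SS_x + SS_err))`, df = n_obs − n_subjects − 1, verified to 1e−10
  against per-subject centering.
* **Feature selection.** An EEG feature enters the report only if it is
  significant in at least one LMM trial contrast *and* at least one
  repeated-measures correlation with behavior.
* **Session comparison.** Last trial of one session vs first trial of the
  next, paired by participant; normality of the paired differences gates
  between the paired t-test and the exact Wilcoxon, feature by feature.
* **Power analysis.** Smallest n whose two-sided paired t-test at level α
  reaches the target power under the noncentral t with noncentrality
  d·√n; `sample_size_paired(0.8)` returns the classical 15.

## What the replication ensembles check

Three seeded ensembles (100 seeds each, 20-s trials, one biomarker
pretrained on a fixed external calibration corpus) mirror the three
experiment designs:

* **Same-session practice** must show, as sign patterns of the LMM
  contrasts: economy up, time down, biomarker down, delta down — in at
  least 90% of seeds; the load-uncoupled beta band must fail the dual
  selection rule in at least 90%.
* **Next-day plateau** is a true null: rather than demanding that every
  one of a dozen tests per seed stays non-significant (which a true null
  fails routinely by construction), the ensemble checks that per-contrast
  rejection *rates* across seeds sit near the nominal 5% level, for both
  the within-session contrasts and the paired last-trial/first-trial
  comparison.
* **Daily trials** must dissociate: all three behavioral third-trial
  effects significant in at least 80% of seeds, while the EEG features'
  rejection rate stays near nominal.

## Known limitations

The generator's affine load couplings and stationary per-trial spectra
are the simplest forms consistent with the monotone relationships the
analysis consumes; it does not model artifacts, habituation within a
trial, inter-trial break effects on baseline, or demographic covariates.
The EDF codec is deliberately minimal (single signal, 1-s records,
pinned timestamps) — enough for lossless round-trips of the package's own
recordings, not a general-purpose biosignal reader. Published coefficient
tables from the motivating study were computed on a restricted dataset
and are reproducible here only at the level of signs, calibration rates,
and validity properties.
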