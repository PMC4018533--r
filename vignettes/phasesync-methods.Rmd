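---
title: "Methods: phase-synchrony connectivity with phasesync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-synchrony connectivity with phasesync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself compute.

## The analysis model

The pipeline targets multi-trial source-space ROI time courses from a 2
(listening condition: passive, active) × 2 (stimulus type: intact, noisy)
within-subject design, epoched −200…+500 ms around stimulus onset at
1000 Hz. Five stages follow the epochs:

1. **Preprocessing.** Per trial and ROI, the mean over the 200 ms
   prestimulus baseline is subtracted. Trials whose baseline-corrected peak
   absolute amplitude exceeds a threshold on any ROI (or an auxiliary
   channel) are rejected; the amplitude statistic is measured relative to
   the prestimulus baseline mean. Trial counts are then equalized across
   condition × stimulus cells by uniform random subsampling to the minimum
   cell size, so the across-trial synchrony estimator carries identical
   finite-sample bias in every cell. Subsampling (rather than truncation)
   avoids confounding retained trials with time-in-session.

2. **Time–frequency decomposition.** A continuous complex Morlet wavelet
   transform at 25 center frequencies, 8–80 Hz in 3 Hz steps. The cycle
   count grows linearly with frequency, `cycles(f) = f / 7`, giving 1.14
   cycles at 8 Hz and 11.43 at 80 Hz (1.1 and 11.4 at display precision).
   Only the linear schedule's endpoints are externally constrained; the
   linear interpolation between them, with divisor 7, is this package's
   declared assumption. Wavelets have Gaussian envelope
   `sigma_t = cycles / (2*pi*f)`, are truncated at ±3.5 σ_t, unit-L2
   normalized, and applied by zero-padded FFT convolution. Samples within
   one half-support of an epoch edge are flagged boundary-affected; at
   1000 Hz with the −200…+500 ms epoch, the 50–200 ms analysis window
   contains no flagged samples at any grid frequency (asserted by test).
   Because only coefficient phases enter the synchrony index, the amplitude
   normalization has no downstream effect.

3. **Connectivity.** The across-trial weighted phase lag index at every
   frequency and sample, `|Σ_k Im X_k| / Σ_k |Im X_k|`, with
   `X_k = a_k conj(b_k)`. The standard (not debiased-square) estimator is
   used, keeping values on [0, 1]. An exactly zero denominator (identical
   signals) is reported as missing, not 0 — zero would assert random phase,
   a different claim. Per-sample WPLI is computed first and then averaged
   into 10-ms windows over 50–200 ms (15 bins); the alternative order
   (averaging cross-spectra first) is a different estimator and is not
   used.

4. **Inference.** Trial-shuffle surrogates permute each ROI's trial order
   independently (1000 shuffles by default), destroying induced
   (trial-varying phase) coupling while preserving stimulus-locked phase
   consistency — the null of regions independently synchronizing to the
   onset. p-values use the add-one convention `(1 + #{null ≥ obs}) /
   (1 + N)`, which cannot return 0 and is conservative relative to the raw
   exceedance percentage. Group statistics: each 2×2 repeated-measures
   effect is a within-subject contrast whose squared one-sample t equals
   the textbook sums-of-squares RM-ANOVA F with df (1, n−1) (asserted
   against an independent `aov()` oracle); the noisy-vs-intact contrast is
   also run one-way within the passive condition. Spearman correlations
   (mid-ranks, t approximation for p at n ≈ 20, permutation p optional)
   relate synchrony to identification accuracy. Benjamini–Hochberg FDR is
   applied per test family (one family per test type across all connection
   × time × frequency comparisons). Behavioral sensitivity is
   `d' = z(hit) − z(FA)`; rates of exactly 0/1 are rescued by the
   log-linear count correction `(count + 0.5)/(N + 1)`.

5. **Directionality (SEM).** The observed vector is
   `(y_t, x_{t−τ})` for the analyzed nodes, built from the real part of the
   band-averaged wavelet coefficients in the effect's time window,
   standardized per trial × node — the same representation as the synchrony
   effect it follows up. Pairwise: `β_A→B` is the pooled least-squares
   coefficient of `B(t)` on `A(t−τ)`; bootstrap confidence intervals
   resample **trials**, because consecutive samples are serially dependent;
   the group test is a paired sign-flip permutation t-test (10,000 flips)
   on `β_A→B − β_B→A`. Loop models: all `2^3 = 8` orientations of the
   three-node triangle, each edge carrying exactly one direction so every
   candidate has the same degrees of freedom. Free parameters: one path per
   edge (3), endogenous residual variances (3), and the saturated exogenous
   lagged covariance block (6) — 12 parameters against 21 moments, df = 9.
   The ML discrepancy `F_ML = ln|Σ(θ)| + tr(S Σ(θ)^-1) − ln|S| − p` is
   minimized by BFGS from regression-based starting values (up to 3
   jittered restarts), `χ² = (N_eff − 1) F_ML` with the **trial count** as
   effective sample size (not the serially dependent pooled sample count),
   and `RMSEA = sqrt(max(χ² − df, 0)/(df (N_eff − 1)))`, cutoff 0.07.

A zero-lag reciprocal two-node SEM is unidentified; the lagged formulation
is what makes both the reciprocal pairwise models and the loop models
identifiable with positive df. This is the package's declared
reconstruction of an underdetermined analysis choice; τ defaults to a
quarter cycle at the effect's center frequency (e.g. 12 samples at ~20 Hz
and 1000 Hz), matching the delay at which a quarter-cycle phase-lagged
influence is maximally visible to a lagged regression.

## The synthetic-data generator

`generate_subject()` builds each ROI trace as the sum of:

* **1/f background noise** — white Gaussian noise spectrally shaped to
  power ∝ 1/f above 1 Hz (flat below), unit variance. Real source noise has
  subject- and region-specific spectral exponents and nonstationarities
  that this deliberately does not model.
* an optional **evoked component** — a 10 Hz damped cosine (decay constant
  50 ms) starting at +50 ms, with identical phase on every trial. This is
  the component that makes the trial-shuffle null non-trivial: it survives
  shuffling, induced coupling does not.
* the **induced couplings** — per `coupling_spec`, a sinusoid at the center
  frequency with a fresh uniform phase per trial, injected into both ROIs,
  the second copy delayed by `phase_lag/(2πf)` seconds (a physical
  conduction delay rather than an analytic-signal rotation), scaled by
  `coupling_strength × subject_kappa`, and gated to the coupling window
  with 10-ms cosine ramps.

`generate_cohort()` draws per-subject gains κ_s from log-normal(0, 0.5) —
strictly positive, right-skewed inter-subject variation — and sets
accuracy = base + slope·κ_s + Gaussian noise, clipped to [0, 1]. Defaults
(base 0.55, slope 0.15, noise SD 0.05) put the cohort mean near the ~70 %
noisy-syllable identification level typical of such tasks. The default
design is 20 subjects and 75 trials per condition × stimulus × token cell
(2 conditions × 2 stimulus types × 2 syllable tokens → 300 trials per
condition); analyses pool tokens within each condition × stimulus cell.

What a green test therefore establishes: the estimators recover planted
coupling structure, direction, and behavior linkage from data with the
stated noise model, and stay calibrated under the matched nulls (no
coupling, zero-lag mixing, evoked-only). What it does not establish:
performance under real source-leakage geometry, non-sinusoidal or
nonstationary oscillations, artifact topographies, or inverse-modeling
errors — none of which the generator emulates.

## Numerical choices and degenerate inputs

* Epoch convention: half-open `[−200, +500)` ms at 1000 Hz → 700 samples,
  onset at sample index 201 (1-based).
* WPLI needs ≥ 2 trials (error otherwise); 0/0 is flagged missing and
  excluded from window means; a window is missing only if all its samples
  are.
* Window averaging errors when bin edges do not align with the sample grid
  rather than silently interpolating.
* Rejection with every trial above threshold is an error (downstream
  estimators undefined), as is an empty baseline window.
* `fdr_correct()` accepts p = 0: a perfect monotone Spearman relation at,
  e.g., saturated WPLI yields p → 0 under the t approximation.
* SEM: singular sample covariance and non-convergence after 3 jittered
  restarts are labeled errors; `χ² ≤ df` floors RMSEA at exactly 0.
* All stages are seeded; the pipeline derives per-stage seeds from one
  master seed, so a rerun with the same config reproduces every table.

## Scaling of the stochastic test suites

Monte-Carlo calibration tests (surrogate type-I rate, sign-flip test
type-I rate, end-to-end correlation power) run at reduced replicate counts
(25–60 replicates, 99–999 resamples) with acceptance bands widened only to
the corresponding binomial confidence width, to keep the default suite
within a desktop time budget. The estimators under test are identical at
production settings (1000 shuffles, 10,000 flips); only replicate counts
are scaled.

## Known limitations

* The WPLI path estimates synchrony across trials only; within-trial
  (time-resolved single-trial) synchrony is out of scope.
* The SEM stage fits observed-variable lagged path models; latent-variable
  SEM, Granger causality and transfer entropy are out of scope.
* Loop-model comparison assumes every candidate has identical df; models
  with different connectivity cardinality are deliberately not compared.
* Serialization uses CSV/JSON (and RDS for intermediate CLI artifacts);
  no HDF5 bindings are assumed in the environment.
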