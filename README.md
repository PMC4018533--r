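# phasesync

Inter-areal phase-synchrony connectivity analysis for multi-trial
electrophysiological source data, in R.

In MEG/EEG source-space experiments, oscillatory coupling between cortical
regions of interest (ROIs) is commonly quantified by the **weighted phase
lag index** computed across trials at each time–frequency point,

    WPLI(f, t) = | Σ_k Im X_k(f, t) |  /  Σ_k | Im X_k(f, t) | ,

where `X_k = a_k · conj(b_k)` is the cross-spectrum of the two ROIs' complex
Morlet wavelet coefficients on trial `k`. Weighting phase leads and lags by
the magnitude of the imaginary cross-spectrum makes the index insensitive to
zero-lag mixing (volume conduction): WPLI is 1 for a constant non-zero phase
lag across trials and 0 for randomly distributed phases. Because regions can
also appear synchronized merely by each phase-locking to the stimulus onset,
observed values are tested against a **trial-shuffle surrogate null** (each
ROI's trial order permuted independently, 1000 times). Group inference uses
within-subject contrast F tests (algebraically the 2×2 repeated-measures
ANOVA), Spearman correlation with behavioral accuracy, and Benjamini–Hochberg
FDR across all connection × time × frequency comparisons. Directionality is
assessed post hoc by **lagged structural equation models**: per-subject path
coefficients β of each region on its presumed source at `t − τ`, a paired
sign-flip permutation t-test on β_A→B − β_B→A, and χ²/RMSEA comparison of the
8 unidirectional three-node loop models,
`RMSEA = sqrt(max(χ² − df, 0) / (df · (N − 1)))` with < 0.07 read as good fit.

The package ships a synthetic-data generator that emulates the study design
the pipeline targets — 20 subjects, 2 listening conditions × 2 stimulus
types × 2 syllable tokens × 75 trials, epochs −200…+500 ms at 1000 Hz, 1/f
background noise, stimulus-locked evoked components, band-limited
phase-lagged coupling, and behavior linked to coupling gain — so every stage
is testable end to end with known ground truth.

## Worked example

Plant one beta-band (20 Hz) coupling between auditory cortex and ventral
premotor cortex with a quarter-cycle lag, let its per-subject gain drive
identification accuracy, and run the full pipeline:

```r
library(phasesync)

design   <- study_design(n_subjects = 12, trials_per_cell = 20,
                         rois = c("AC-lh", "vPMC-lh", "TPJ-lh"))
coupling <- coupling_spec(c("AC-lh", "vPMC-lh"), center_frequency = 20,
                          phase_lag = pi / 2, coupling_strength = 1.5)
config   <- pipeline_config(design = design, couplings = list(coupling),
                            behavioral = behavioral_spec(0.55, 0.15, 0.05),
                            grid = frequency_grid(14, 26, 3),
                            n_shuffles = 500, n_boot = 200, n_perm = 2000,
                            seed = 7)
report <- run_pipeline(config)
report
#> <pipeline_report>
#>   10800 group-table rows; 900 effect tests; 225 correlations
#>   FDR-significant effects: 0; correlations: 36
#>   directionality: AC-lh--vPMC-lh t = 11.49, p = 0.0005
```

The synchrony–behavior correlation is recovered at the planted pair, and the
trial-shuffle surrogate confirms it reflects induced coupling rather than
stimulus-locked phase resetting:

```r
report$correlations[which.min(report$correlations$p_fdr), ]
#>             pair frequency window_start    r        p   p_fdr
#> 1 AC-lh--vPMC-lh        14           50 0.93 1.17e-05 0.00132
report$surrogates
#>             pair frequency window_start  statistic observed     p
#> 1 AC-lh--vPMC-lh        14           50 spearman_r     0.93 0.002
```

(the 14 Hz label is one 3-Hz grid step from the planted 20 Hz; at these
few-cycle wavelet widths neighbouring frequency bins overlap heavily). The
pairwise SEM stage calls the planted direction:

```r
report$directionality
#>             pair lag    t     p mean_beta_ab mean_beta_ba
#> 1 AC-lh--vPMC-lh  18 11.5 5e-04        0.559       -0.538
```

No condition/stimulus ANOVA effect is flagged — the planted coupling is
identical in all four cells, so that family is null by construction.

A command-line front end with `simulate`, `preprocess`, `tfr`, `wpli`,
`surrogate`, `stats`, `sem` and `run-all` subcommands is installed at
`inst/cli/phasesync` (JSON config, CSV/RDS artifacts).

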