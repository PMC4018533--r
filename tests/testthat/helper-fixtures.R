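# Shared fixtures and independent oracles for the test suite.

# Two-ROI epochs of pure sinusoids at frequency f (Hz) with a fixed
# channel delay (ms) and per-trial phases.
sine_pair_epochs <- function(n_trials, f = 20, delay_ms = 12.5,
                             phases = NULL, noise_sd = 0,
                             time = seq(-200, 499, 1), srate = 1000) {
  if (is.null(phases)) phases <- runif(n_trials, 0, 2 * pi)
  dat <- array(0, c(n_trials, 2, length(time)))
  for (k in seq_len(n_trials)) {
    dat[k, 1, ] <- cos(2 * pi * f * time / 1000 + phases[k])
    dat[k, 2, ] <- cos(2 * pi * f * (time - delay_ms) / 1000 + phases[k])
    if (noise_sd > 0)
      dat[k, , ] <- dat[k, , ] + rnorm(2 * length(time), 0, noise_sd)
  }
  epoch_array(dat, time, c("A", "B"), srate)
}

# Small design for generator tests.
small_design <- function(...) {
  study_design(n_subjects = 4, trials_per_cell = 10,
               rois = c("AC-lh", "vPMC-lh", "TPJ-lh"), ...)
}

# Brute-force time-domain Morlet convolution oracle, independent of the
# FFT path: direct O(n*m) sum with zero-padded edges.
naive_morlet <- function(x, f, srate, cycles) {
  w <- morlet_wavelet(f, srate, cycles)
  hs <- attr(w, "half_support")
  n <- length(x)
  out <- complex(n)
  for (t in seq_len(n)) {
    acc <- 0 + 0i
    for (j in -hs:hs) {
      ti <- t - j
      if (ti >= 1 && ti <= n) acc <- acc + x[ti] * w[j + hs + 1]
    }
    out[t] <- acc
  }
  out
}

# Sums-of-squares repeated-measures ANOVA oracle via base aov().
aov_rm_oracle <- function(df) {
  df$subject <- factor(df$subject)
  df$condition <- factor(df$condition)
  df$stimulus <- factor(df$stimulus)
  fit <- summary(aov(value ~ condition * stimulus +
                       Error(subject / (condition * stimulus)), data = df))
  get_f <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(condition_main = get_f("Error: subject:condition", "condition"),
    stimulus_main = get_f("Error: subject:stimulus", "stimulus"),
    interaction = get_f("Error: subject:condition:stimulus",
                        "condition:stimulus"))
}

# Random 2x2 within-subject table.
random_rm_table <- function(n_subjects, effect = 0) {
  g <- expand.grid(subject = sprintf("s%02d", seq_len(n_subjects)),
                   condition = c("c1", "c2"), stimulus = c("s1", "s2"),
                   stringsAsFactors = FALSE)
  g$value <- rnorm(nrow(g)) + effect * (g$condition == "c2")
  g
}
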