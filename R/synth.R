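#' 1/f ("pink") background noise
#'
#' Synthesizes noise traces by spectral shaping of Gaussian white noise:
#' amplitude scaled as 1/sqrt(f) (power proportional to 1/f) for f >= 1 Hz,
#' flat below 1 Hz, each trace normalized to unit standard deviation.
#' Uses the current RNG state.
#'
#' @param n_samples samples per trace
#' @param n_traces number of traces
#' @param srate sampling rate in Hz
#' @return numeric matrix n_samples x n_traces
#' @export
pink_noise <- function(n_samples, n_traces = 1, srate = 1000) {
  stopifnot(n_samples >= 2, n_traces >= 1)
  w <- matrix(stats::rnorm(n_samples * n_traces), n_samples, n_traces)
  f <- srate * (seq_len(n_samples) - 1) / n_samples
  f <- pmin(f, srate - f)              # two-sided spectrum, symmetric filter
  h <- 1 / sqrt(pmax(f, 1))            # power ~ 1/f above 1 Hz, flat below
  h[1] <- 0                            # remove DC
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n_samples
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

# Damped-cosine evoked component, identical across trials: phase-locked to
# stimulus onset, 10 Hz carrier, 50 ms decay constant, onset at +50 ms.
evoked_component <- function(time, amplitude = 1, freq = 10,
                             onset = 50, decay = 50) {
  tt <- time - onset
  out <- numeric(length(time))
  on <- tt >= 0
  out[on] <- amplitude * exp(-tt[on] / decay) * cos(2 * pi * freq * tt[on] / 1000)
  out
}

# Cosine-ramp gate over `window` (ms) with `ramp` ms raised-cosine edges.
cosine_gate <- function(time, window, ramp = 10) {
  g <- numeric(length(time))
  inside <- time >= window[1] & time < window[2]
  g[inside] <- 1
  if (ramp > 0) {
    up <- time >= window[1] & time < window[1] + ramp
    g[up] <- 0.5 * (1 - cos(pi * (time[up] - window[1]) / ramp))
    dn <- time >= window[2] - ramp & time < window[2]
    g[dn] <- 0.5 * (1 - cos(pi * (window[2] - time[dn]) / ramp))
  }
  g
}

#' Generate one subject's synthetic epochs
#'
#' Each ROI trace is the sum of unit-variance 1/f background noise, an
#' optional stimulus-locked evoked component (identical phase across
#' trials), and the induced coupled components described by `couplings`:
#' a source oscillator at the coupling's center frequency with a fresh
#' uniform random phase on every trial is injected into both ROIs of the
#' pair, the second copy delayed by the coupling's phase lag (as a time
#' shift, i.e. a conduction delay), scaled by
#' `coupling_strength * subject_kappa` and gated to the coupling window
#' with cosine-ramped edges. Bit-reproducible for a given seed.
#'
#' @param design a [study_design()]
#' @param couplings list of [coupling_spec()] objects (possibly empty)
#' @param subject_kappa subject-level coupling gain multiplier
#' @param seed integer seed
#' @param evoked_amplitude amplitude of the evoked component relative to
#'   the unit-variance noise; 0 disables
#' @param subject subject identifier stored in the result
#' @return an [epoch_array()]
#' @export
generate_subject <- function(design, couplings = list(), subject_kappa = 1,
                             seed = 1L, evoked_amplitude = 1,
                             subject = "S01") {
  stopifnot(inherits(design, "study_design"))
  for (cs in couplings) {
    if (!all(cs$roi_pair %in% design$rois))
      stop(sprintf("coupling references unknown ROI(s): %s",
                   paste(setdiff(cs$roi_pair, design$rois), collapse = ", ")),
           call. = FALSE)
    if (cs$coupling_window[1] < design$epoch_window[1] ||
        cs$coupling_window[2] > design$epoch_window[2])
      stop("coupling_window lies outside the epoch window", call. = FALSE)
  }
  time <- design_time_axis(design)
  ns <- length(time)
  tab <- design_trial_table(design)
  ntr <- nrow(tab)
  nroi <- length(design$rois)

  set.seed(seed)
  noise <- pink_noise(ns, ntr * nroi, design$sampling_rate)
  dat <- aperm(array(noise, c(ns, ntr, nroi)), c(2, 3, 1))

  if (evoked_amplitude != 0) {
    ev <- evoked_component(time, evoked_amplitude)
    dat <- dat + rep(ev, each = ntr * nroi)
  }

  for (cs in couplings) {
    if (cs$coupling_strength == 0 || subject_kappa == 0) next
    amp <- cs$coupling_strength * subject_kappa
    f0 <- cs$center_frequency
    delay_ms <- if (cs$directed) cs$direction_lag else
      cs$phase_lag / (2 * pi * f0) * 1000
    gate <- cosine_gate(time, cs$coupling_window)
    ia <- match(cs$roi_pair[1], design$rois)
    ib <- match(cs$roi_pair[2], design$rois)
    phi <- stats::runif(ntr, 0, 2 * pi)
    wt <- 2 * pi * f0 * time / 1000
    wdel <- 2 * pi * f0 * delay_ms / 1000
    for (k in seq_len(ntr)) {
      src <- amp * gate * cos(wt + phi[k])
      src_del <- amp * gate * cos(wt - wdel + phi[k])
      dat[k, ia, ] <- dat[k, ia, ] + src
      dat[k, ib, ] <- dat[k, ib, ] + src_del
    }
  }

  epoch_array(dat, time, design$rois, design$sampling_rate, tab, subject)
}

#' Generate a synthetic cohort with behavior-linked coupling strength
#'
#' Draws per-subject coupling gains kappa_s from a log-normal distribution
#' (strictly positive, right-skewed inter-subject variation), generates each
#' subject's epochs with [generate_subject()], and produces behavioral
#' accuracies `base + slope * kappa_s + noise`, clipped to [0, 1]. The
#' paired output supports recovery of synchrony-behavior correlations.
#'
#' @param design a [study_design()]
#' @param couplings list of [coupling_spec()]
#' @param behavioral a [behavioral_spec()]
#' @param seed integer seed
#' @param kappa_meanlog,kappa_sdlog log-normal parameters for kappa_s
#' @param evoked_amplitude passed to [generate_subject()]
#' @return a list of class `cohort`: one element per subject, each a list
#'   with `epochs` (an `epoch_array`), `accuracy` and `kappa`
#' @export
generate_cohort <- function(design, couplings = list(),
                            behavioral = behavioral_spec(), seed = 1L,
                            kappa_meanlog = 0, kappa_sdlog = 0.5,
                            evoked_amplitude = 1) {
  stopifnot(inherits(design, "study_design"), design$n_subjects >= 2)
  if (kappa_sdlog == 0 && behavioral$accuracy_slope != 0)
    warning("kappa distribution is degenerate (zero variance) with a ",
            "non-zero accuracy slope: correlation is unidentifiable",
            call. = FALSE)
  set.seed(seed)
  n <- design$n_subjects
  kappa <- stats::rlnorm(n, kappa_meanlog, kappa_sdlog)
  acc <- behavioral$base_accuracy + behavioral$accuracy_slope * kappa +
    stats::rnorm(n, 0, behavioral$noise_sd)
  acc <- pmin(pmax(acc, 0), 1)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    out[[s]] <- list(
      epochs = generate_subject(design, couplings, subject_kappa = kappa[s],
                                seed = sub_seeds[s],
                                evoked_amplitude = evoked_amplitude,
                                subject = sprintf("S%02d", s)),
      accuracy = acc[s], kappa = kappa[s])
  }
  class(out) <- "cohort"
  out
}

#' Simulate trials from a directed lagged loop model
#'
#' Generates multi-trial signals that follow a directed lagged path model
#' exactly: each node at time t equals `beta` times its parent's value at
#' t - lag plus white Gaussian innovation noise. Used to validate SEM
#' fitting: data generated this way satisfy the lagged path model's
#' covariance restrictions in population, so the generating model should
#' fit with RMSEA near zero.
#'
#' @param model a loop model from [enumerate_loop_models()]
#' @param n_trials number of trials
#' @param n_samples samples per trial
#' @param beta path coefficient applied on every edge
#' @param lag lag in samples
#' @param innovation_sd innovation (residual) SD
#' @param seed integer seed
#' @return numeric array n_trials x nodes x n_samples (dimnames on nodes)
#' @export
generate_loop_signals <- function(model, n_trials, n_samples, beta = 0.5,
                                  lag = 12, innovation_sd = 1, seed = 1L) {
  stopifnot(inherits(model, "loop_model"), lag >= 1, n_samples > lag)
  nodes <- model$nodes
  k <- length(nodes)
  parents <- loop_parents(model)         # parent indices per node
  set.seed(seed)
  out <- array(0, c(n_trials, k, n_samples), dimnames = list(NULL, nodes, NULL))
  for (tr in seq_len(n_trials)) {
    e <- matrix(stats::rnorm(k * n_samples, 0, innovation_sd), k, n_samples)
    x <- e
    for (t in (lag + 1):n_samples) {
      for (i in seq_len(k)) {
        if (length(parents[[i]]) > 0)
          x[i, t] <- beta * sum(x[parents[[i]], t - lag]) + e[i, t]
      }
    }
    out[tr, , ] <- x
  }
  out
}
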