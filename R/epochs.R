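#' Epoch array: one subject's trials x ROIs x samples
#'
#' The basic container for all downstream computation: a real-valued 3-D
#' array of epoched ROI time courses together with its time axis (ms),
#' sampling rate and per-trial metadata (condition, stimulus type).
#'
#' @param data numeric array, trials x ROIs x samples
#' @param time numeric vector of sample times in ms (length = dim(data)[3])
#' @param rois character vector of ROI labels (length = dim(data)[2])
#' @param srate sampling rate in Hz
#' @param trials data.frame with one row per trial (columns typically
#'   `condition` and `stimulus`); may be `NULL`
#' @param subject subject identifier
#' @return an object of class `epoch_array`
#' @export
epoch_array <- function(data, time, rois, srate, trials = NULL,
                        subject = NA_character_) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trials x ROIs x samples)", call. = FALSE)
  if (dim(data)[2] != length(rois))
    stop("ROI label count does not match dim(data)[2]", call. = FALSE)
  if (dim(data)[3] != length(time))
    stop("time axis length does not match dim(data)[3]", call. = FALSE)
  if (anyDuplicated(rois))
    stop("ROI labels must be unique", call. = FALSE)
  if (!is.null(trials) && nrow(trials) != dim(data)[1])
    stop("trial table rows do not match dim(data)[1]", call. = FALSE)
  dimnames(data) <- list(NULL, rois, NULL)
  structure(
    list(data = data, time = time, rois = rois, srate = srate,
         trials = trials, subject = subject),
    class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> subject=%s: %d trials x %d ROIs x %d samples @ %g Hz\n",
              x$subject, d[1], d[2], d[3], x$srate))
  cat(sprintf("  time: [%g, %g] ms; ROIs: %s\n",
              min(x$time), max(x$time), paste(x$rois, collapse = ", ")))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

#' Subset an epoch array by trial index
#'
#' @param epochs an `epoch_array`
#' @param idx integer vector of trial indices to keep
#' @return an `epoch_array` with the selected trials
#' @export
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_array"))
  epoch_array(epochs$data[idx, , , drop = FALSE], epochs$time, epochs$rois,
              epochs$srate,
              if (!is.null(epochs$trials)) epochs$trials[idx, , drop = FALSE],
              epochs$subject)
}

#' Study design for the synthetic-data generator
#'
#' Describes the multi-subject, multi-condition epoch structure the
#' generator emulates: a 2 (listening condition) x 2 (stimulus type) design
#' with 75 trials per cell, 10 source-space ROIs (5 per hemisphere), epochs
#' spanning -200..+500 ms at 1000 Hz. The epoch window is half-open
#' `[tmin, tmax)` so the default yields exactly 700 samples with stimulus
#' onset (t = 0) at sample index 201.
#'
#' @param n_subjects number of subjects (default 20)
#' @param conditions condition labels (default passive, active)
#' @param stimulus_types stimulus type labels (default intact, noisy)
#' @param tokens syllable token labels within each stimulus type (default
#'   pa, ta), so each condition carries
#'   `trials_per_cell * stimulus_types * tokens` trials (75 x 4 = 300 by
#'   default)
#' @param trials_per_cell trials per condition x stimulus x token cell
#'   (default 75)
#' @param rois ROI labels; default the 10 labels AC/TPJ/vPMC/dPMC/MC per
#'   hemisphere ("-lh"/"-rh")
#' @param epoch_window epoch interval in ms, half-open (default c(-200, 500))
#' @param sampling_rate sampling rate in Hz (default 1000)
#' @param seed integer seed stored with the design
#' @return an object of class `study_design`
#' @export
study_design <- function(n_subjects = 20,
                         conditions = c("passive", "active"),
                         stimulus_types = c("intact", "noisy"),
                         tokens = c("pa", "ta"),
                         trials_per_cell = 75,
                         rois = default_rois(),
                         epoch_window = c(-200, 500),
                         sampling_rate = 1000,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, trials_per_cell >= 1,
            length(epoch_window) == 2, epoch_window[1] < epoch_window[2],
            sampling_rate > 0)
  if (anyDuplicated(c(conditions, stimulus_types)) ||
      anyDuplicated(tokens) || anyDuplicated(rois))
    stop("condition, stimulus and ROI labels must be unique", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         conditions = conditions,
         stimulus_types = stimulus_types,
         tokens = tokens,
         trials_per_cell = as.integer(trials_per_cell),
         rois = rois,
         epoch_window = epoch_window,
         sampling_rate = sampling_rate,
         seed = as.integer(seed)),
    class = "study_design")
}

#' @rdname study_design
#' @export
default_rois <- function() {
  as.vector(outer(c("AC", "TPJ", "vPMC", "dPMC", "MC"), c("lh", "rh"),
                  paste, sep = "-"))
}

# Half-open [tmin, tmax) sample grid in ms.
design_time_axis <- function(design) {
  step <- 1000 / design$sampling_rate
  seq(design$epoch_window[1], design$epoch_window[2] - step, by = step)
}

design_trial_table <- function(design) {
  tab <- expand.grid(rep = seq_len(design$trials_per_cell),
                     token = design$tokens,
                     stimulus = design$stimulus_types,
                     condition = design$conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(condition = tab$condition, stimulus = tab$stimulus,
             token = tab$token, stringsAsFactors = FALSE)
}

#' Specification of one induced oscillatory coupling between two ROIs
#'
#' Describes a band-limited source oscillator with per-trial random phase
#' injected into both ROIs of a pair, the second copy delayed so that the
#' pair carries a fixed non-zero phase lag -- the signature a phase-lag
#' index is designed to detect, and the kind of lag a physical conduction
#' delay between brain areas produces. `phase_lag = 0` creates a shared
#' zero-lag (volume-conduction-like) source, useful as a robustness fixture.
#'
#' @param roi_pair ordered pair of ROI labels (source first)
#' @param center_frequency oscillator frequency in Hz
#' @param phase_lag phase lag of the second ROI relative to the first, in
#'   radians; applied as a time shift `phase_lag / (2*pi*f)`
#' @param coupling_window interval in ms during which the coupling is
#'   active (cosine-ramped edges)
#' @param coupling_strength amplitude of the injected oscillation relative
#'   to the unit-variance background noise (kappa >= 0; 0 disables)
#' @param directed if `TRUE` the second ROI receives the source with a
#'   causal delay of `direction_lag` ms (for directed-influence tests)
#' @param direction_lag delay in ms used when `directed = TRUE`
#' @return an object of class `coupling_spec`
#' @export
coupling_spec <- function(roi_pair, center_frequency, phase_lag = pi / 2,
                          coupling_window = c(50, 200),
                          coupling_strength = 1,
                          directed = FALSE, direction_lag = NULL) {
  stopifnot(length(roi_pair) == 2, center_frequency > 0,
            coupling_strength >= 0,
            length(coupling_window) == 2,
            coupling_window[1] < coupling_window[2])
  if (directed && is.null(direction_lag))
    stop("`direction_lag` must be given when directed = TRUE", call. = FALSE)
  structure(
    list(roi_pair = roi_pair, center_frequency = center_frequency,
         phase_lag = phase_lag, coupling_window = coupling_window,
         coupling_strength = coupling_strength, directed = directed,
         direction_lag = direction_lag),
    class = "coupling_spec")
}

#' Behavioral model linking coupling strength to task accuracy
#'
#' Across-subject covariation between a subject's overall coupling gain
#' kappa_s and their syllable-identification accuracy:
#' `accuracy = base + slope * kappa_s + N(0, noise_sd)`, clipped to [0, 1].
#'
#' @param base_accuracy intercept, proportion correct
#' @param accuracy_slope change in proportion correct per unit kappa
#' @param noise_sd SD of the additive Gaussian accuracy noise
#' @return an object of class `behavioral_spec`
#' @export
behavioral_spec <- function(base_accuracy = 0.55, accuracy_slope = 0.15,
                            noise_sd = 0.05) {
  stopifnot(base_accuracy >= 0, base_accuracy <= 1, noise_sd >= 0)
  structure(list(base_accuracy = base_accuracy,
                 accuracy_slope = accuracy_slope,
                 noise_sd = noise_sd),
            class = "behavioral_spec")
}
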