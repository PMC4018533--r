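#' Rejection criteria for amplitude-based trial rejection
#'
#' Amplitude thresholds measured on baseline-corrected traces (the peak
#' absolute value relative to the prestimulus baseline mean). The signal
#' threshold is the stand-in for a gradiometer criterion such as 3000
#' fT/cm; the aux threshold for an EOG-style auxiliary channel criterion.
#'
#' @param signal_threshold amplitude threshold for the ROI channels
#' @param aux_threshold amplitude threshold for the auxiliary channel
#' @param baseline_window baseline interval in ms, half-open
#' @return an object of class `rejection_criteria`
#' @export
rejection_criteria <- function(signal_threshold, aux_threshold = Inf,
                               baseline_window = c(-200, 0)) {
  stopifnot(signal_threshold > 0, aux_threshold > 0,
            length(baseline_window) == 2,
            baseline_window[1] < baseline_window[2])
  structure(list(signal_threshold = signal_threshold,
                 aux_threshold = aux_threshold,
                 baseline_window = baseline_window),
            class = "rejection_criteria")
}

baseline_index <- function(time, baseline_window) {
  idx <- which(time >= baseline_window[1] & time < baseline_window[2])
  if (length(idx) == 0)
    stop("baseline window contains no samples", call. = FALSE)
  idx
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and ROI, the mean over the baseline samples (the
#' prestimulus period by default), so that the baseline mean of the output
#' is zero to numerical tolerance.
#'
#' @param epochs an [epoch_array()]
#' @param baseline_window interval in ms, half-open (default the full
#'   200 ms prestimulus period)
#' @return baseline-corrected `epoch_array`
#' @export
baseline_correct <- function(epochs, baseline_window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_array"))
  idx <- baseline_index(epochs$time, baseline_window)
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(bl)   # recycles over the sample axis
  out
}

#' Reject trials exceeding amplitude thresholds
#'
#' A trial is dropped iff its maximum absolute baseline-corrected amplitude
#' on any ROI exceeds `signal_threshold`, or on the auxiliary channel
#' exceeds `aux_threshold`. The returned log records, for each rejected
#' trial, the offending channel, its peak and the threshold it exceeded.
#'
#' @param epochs an [epoch_array()]
#' @param criteria a [rejection_criteria()]
#' @param aux optional trials x samples matrix of an auxiliary channel
#' @return list with `epochs` (retained trials) and `log` (data.frame:
#'   trial, channel, peak, threshold, reason)
#' @export
reject_trials <- function(epochs, criteria, aux = NULL) {
  stopifnot(inherits(epochs, "epoch_array"),
            inherits(criteria, "rejection_criteria"))
  bc <- baseline_correct(epochs, criteria$baseline_window)
  peaks <- apply(abs(bc$data), c(1, 2), max)       # trials x ROIs
  worst <- apply(peaks, 1, max)
  worst_roi <- epochs$rois[apply(peaks, 1, which.max)]
  bad_sig <- worst > criteria$signal_threshold

  bad_aux <- rep(FALSE, n_trials(epochs))
  aux_peak <- rep(NA_real_, n_trials(epochs))
  if (!is.null(aux)) {
    idx <- baseline_index(epochs$time, criteria$baseline_window)
    aux_bc <- aux - rowMeans(aux[, idx, drop = FALSE])
    aux_peak <- apply(abs(aux_bc), 1, max)
    bad_aux <- aux_peak > criteria$aux_threshold
  }

  bad <- bad_sig | bad_aux
  if (all(bad))
    stop("all trials rejected; downstream estimates undefined", call. = FALSE)

  log <- data.frame(
    trial = which(bad),
    channel = ifelse(bad_sig[bad], worst_roi[bad], "aux"),
    peak = ifelse(bad_sig[bad], worst[bad], aux_peak[bad]),
    threshold = ifelse(bad_sig[bad], criteria$signal_threshold,
                       criteria$aux_threshold),
    reason = ifelse(bad_sig[bad], "signal_amplitude", "aux_amplitude"),
    stringsAsFactors = FALSE)

  list(epochs = subset_trials(epochs, which(!bad)), log = log)
}

#' Equalize trial counts across groups
#'
#' Subsamples every group without replacement, uniformly at random, to the
#' minimum group size, so the across-trial synchrony estimator carries the
#' same finite-sample bias in every group. Trial order within each group is
#' otherwise preserved. Deterministic given the seed.
#'
#' @param groups list of [epoch_array()] objects (>= 2)
#' @param seed integer seed
#' @return list of `epoch_array` objects, all with the minimum trial count
#' @export
equalize_trial_counts <- function(groups, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- vapply(groups, n_trials, integer(1))
  if (any(sizes == 0)) stop("empty group", call. = FALSE)
  m <- min(sizes)
  set.seed(seed)
  lapply(groups, function(g) {
    keep <- sort(sample.int(n_trials(g), m))
    subset_trials(g, keep)
  })
}

#' Split an epoch array into condition x stimulus cells
#'
#' @param epochs an [epoch_array()] with a trial table containing
#'   `condition` and `stimulus` columns
#' @return named list of `epoch_array` objects, one per cell
#'   ("condition.stimulus")
#' @export
split_cells <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"), !is.null(epochs$trials))
  key <- interaction(epochs$trials$condition, epochs$trials$stimulus,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(seq_len(n_trials(epochs)), key), function(i)
    subset_trials(epochs, i))
}
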