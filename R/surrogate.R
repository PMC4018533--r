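#' Shuffle trial order independently per ROI
#'
#' Permutes the trial axis of each ROI's wavelet coefficients with an
#' independent uniform random permutation, leaving time and frequency
#' untouched. Because the transform is per-trial, shuffling coefficients is
#' equivalent to shuffling the raw trials before transforming, and avoids
#' recomputing the transform for every surrogate. The shuffle destroys
#' induced (trial-varying phase) coupling between ROIs while preserving any
#' stimulus-locked (evoked) phase consistency within each ROI -- exactly
#' the null of "regions independently synchronizing to the stimulus onset".
#'
#' @param tf a `tf_cube`
#' @param seed integer seed (`NULL` uses the current RNG state)
#' @return a `tf_cube` with trial order permuted per ROI
#' @export
shuffle_trials <- function(tf, seed = NULL) {
  stopifnot(inherits(tf, "tf_cube"))
  ntr <- dim(tf$coef)[1]
  if (ntr < 2) stop("need at least 2 trials to shuffle", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- tf
  for (r in seq_along(tf$rois)) {
    perm <- sample.int(ntr)
    out$coef[, r, , ] <- tf$coef[perm, r, , , drop = FALSE]
  }
  out
}

#' Summary WPLI statistic over a frequency x time region
#'
#' Mean windowed WPLI over the requested frequency and window range for one
#' pair; the default observable entering the surrogate test.
#'
#' @param tf a `tf_cube`
#' @param pair two ROI labels
#' @param freq_range interval in Hz (inclusive)
#' @param window_range,width passed to [window_average()]
#' @return scalar mean WPLI (NA if undefined everywhere)
#' @export
wpli_statistic <- function(tf, pair, freq_range = range(tf$freqs),
                           window_range = c(50, 200), width = 10) {
  sl <- pair_slices(tf, pair, freq_range)
  wpli_stat_slices(sl$a, sl$b, tf$time, window_range, width)
}

# Coefficient slices (trials x freqs x samples) for the two ROIs of a pair,
# restricted to a frequency range; the kernel shared by the statistic and
# the fast surrogate loop.
pair_slices <- function(tf, pair, freq_range) {
  ia <- match(pair[1], tf$rois); ib <- match(pair[2], tf$rois)
  if (is.na(ia) || is.na(ib)) stop("unknown ROI label(s)", call. = FALSE)
  jf <- which(tf$freqs >= freq_range[1] & tf$freqs <= freq_range[2])
  if (length(jf) == 0) stop("empty frequency range", call. = FALSE)
  d <- dim(tf$coef)
  list(a = array(tf$coef[, ia, jf, , drop = FALSE], c(d[1], length(jf), d[4])),
       b = array(tf$coef[, ib, jf, , drop = FALSE], c(d[1], length(jf), d[4])))
}

wpli_stat_slices <- function(a, b, time, window_range, width) {
  w <- wpli(a * Conj(b))
  wa <- window_average(w, time, window_range, width)
  mean(wa$wpli, na.rm = TRUE)
}

#' Trial-shuffle surrogate test for a synchrony statistic
#'
#' Builds a null distribution by recomputing the statistic on `n_shuffles`
#' surrogate datasets in which each ROI's trials are independently
#' reordered, then compares the observed value against it. The p-value uses
#' the add-one convention p = (1 + #\{null >= observed\}) / (1 + n_shuffles),
#' which never returns exactly zero and is conservative relative to the raw
#' exceedance proportion. The null "regions independently synchronizing to
#' the stimulus onset" is rejected when p < 0.05.
#'
#' @param tf a `tf_cube`
#' @param pair two ROI labels
#' @param statistic function `tf -> scalar`; default [wpli_statistic()]
#'   restricted by `...`
#' @param n_shuffles number of surrogate trial orders (default 1000)
#' @param seed integer seed
#' @param ... passed to the default statistic
#' @return object of class `surrogate_result`: `observed`, `null_values`,
#'   `p_value`, `statistic_kind`, `n_shuffles`
#' @export
surrogate_test <- function(tf, pair, statistic = NULL, n_shuffles = 1000,
                           seed = 1L, ...) {
  stopifnot(inherits(tf, "tf_cube"))
  set.seed(seed)
  if (is.null(statistic)) {
    # fast path: permute only the two ROI slices of the default statistic
    dots <- list(...)
    freq_range <- if (!is.null(dots$freq_range)) dots$freq_range
                  else range(tf$freqs)
    window_range <- if (!is.null(dots$window_range)) dots$window_range
                    else c(50, 200)
    width <- if (!is.null(dots$width)) dots$width else 10
    sl <- pair_slices(tf, pair, freq_range)
    ntr <- dim(sl$a)[1]
    observed <- wpli_stat_slices(sl$a, sl$b, tf$time, window_range, width)
    if (!is.finite(observed))
      stop("observed statistic is undefined", call. = FALSE)
    null_values <- vapply(seq_len(n_shuffles), function(i) {
      pa <- sample.int(ntr); pb <- sample.int(ntr)
      wpli_stat_slices(sl$a[pa, , , drop = FALSE],
                       sl$b[pb, , , drop = FALSE],
                       tf$time, window_range, width)
    }, numeric(1))
  } else {
    observed <- statistic(tf)
    if (!is.finite(observed))
      stop("observed statistic is undefined", call. = FALSE)
    null_values <- vapply(seq_len(n_shuffles),
                          function(i) statistic(shuffle_trials(tf)),
                          numeric(1))
  }
  p <- (1 + sum(null_values >= observed, na.rm = TRUE)) / (1 + n_shuffles)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, statistic_kind = "wpli",
                 n_shuffles = n_shuffles),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> %s: observed = %.4f, p = %.4g (%d shuffles)\n",
              x$statistic_kind, x$observed, x$p_value, x$n_shuffles))
  invisible(x)
}

#' Trial-shuffle surrogate test for a synchrony-behavior correlation
#'
#' For each surrogate, trials are reshuffled independently within every
#' subject (and ROI), the per-subject WPLI statistic is recomputed, and the
#' Spearman correlation with the behavioral scores is re-evaluated; the
#' observed correlation is compared against this null with the add-one
#' p-value.
#'
#' @param tf_list list of per-subject `tf_cube` objects
#' @param scores numeric behavioral score per subject
#' @param pair two ROI labels
#' @param n_shuffles number of surrogates
#' @param seed integer seed
#' @param freq_range interval in Hz (default: the full grid)
#' @param window_range,width passed to [window_average()]
#' @return a `surrogate_result` with `statistic_kind = "spearman_r"`
#' @export
surrogate_correlation_test <- function(tf_list, scores, pair,
                                       n_shuffles = 1000, seed = 1L,
                                       freq_range = NULL,
                                       window_range = c(50, 200),
                                       width = 10) {
  stopifnot(length(tf_list) == length(scores), length(scores) >= 5)
  if (is.null(freq_range)) freq_range <- range(tf_list[[1]]$freqs)
  slices <- lapply(tf_list, pair_slices, pair = pair,
                   freq_range = freq_range)
  obs_w <- vapply(seq_along(slices), function(s)
    wpli_stat_slices(slices[[s]]$a, slices[[s]]$b, tf_list[[s]]$time,
                     window_range, width), numeric(1))
  observed <- spearman_correlation(obs_w, scores)$r
  if (!is.finite(observed))
    stop("observed correlation is undefined", call. = FALSE)
  set.seed(seed)
  null_values <- vapply(seq_len(n_shuffles), function(i) {
    w <- vapply(seq_along(slices), function(s) {
      ntr <- dim(slices[[s]]$a)[1]
      pa <- sample.int(ntr); pb <- sample.int(ntr)
      wpli_stat_slices(slices[[s]]$a[pa, , , drop = FALSE],
                       slices[[s]]$b[pb, , , drop = FALSE],
                       tf_list[[s]]$time, window_range, width)
    }, numeric(1))
    spearman_correlation(w, scores)$r
  }, numeric(1))
  p <- (1 + sum(null_values >= observed, na.rm = TRUE)) / (1 + n_shuffles)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, statistic_kind = "spearman_r",
                 n_shuffles = n_shuffles),
            class = "surrogate_result")
}
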