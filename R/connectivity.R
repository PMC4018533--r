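#' Cross-spectrum between two ROIs
#'
#' Per trial k, frequency and sample: X_k(f, t) = a_k(f, t) * Conj(b_k(f, t)),
#' the product of the first ROI's wavelet coefficient with the conjugate of
#' the second's. The phase of X is the inter-ROI phase difference; its
#' imaginary part is the quantity whose sign and magnitude the WPLI weighs.
#'
#' @param tf a `tf_cube` from [morlet_transform()]
#' @param pair character vector of two ROI labels
#' @return complex array trials x frequencies x samples
#' @export
cross_spectrum <- function(tf, pair) {
  stopifnot(inherits(tf, "tf_cube"), length(pair) == 2)
  ia <- match(pair[1], tf$rois)
  ib <- match(pair[2], tf$rois)
  if (is.na(ia) || is.na(ib))
    stop(sprintf("unknown ROI label(s): %s",
                 paste(pair[is.na(c(ia, ib))], collapse = ", ")), call. = FALSE)
  d <- dim(tf$coef)
  x <- tf$coef[, ia, , , drop = FALSE] * Conj(tf$coef[, ib, , , drop = FALSE])
  array(x, d[-2])
}

#' Weighted phase lag index across trials
#'
#' WPLI(f, t) = |sum_k Im X_k| / sum_k |Im X_k|, taken across trials k.
#' Phase leads and lags contribute weighted by the magnitude of the
#' imaginary cross-spectrum, which makes the index insensitive to zero-lag
#' (volume-conducted) coupling: 1 indicates a constant non-zero-lag phase
#' difference on every trial, 0 a random phase distribution. If the
#' denominator is exactly zero (all imaginary parts zero, e.g. identical
#' signals) the estimate is undefined and returned as `NA`, not 0 -- zero
#' would assert random phase, a different claim.
#'
#' @param cross complex array trials x frequencies x samples (or trials x
#'   anything), from [cross_spectrum()]
#' @return numeric array of the trailing dimensions, values in [0, 1] or
#'   `NA` where undefined
#' @export
wpli <- function(cross) {
  d <- dim(cross)
  if (is.null(d)) d <- c(length(cross), 1L)
  if (d[1] < 2)
    stop("WPLI requires at least 2 trials", call. = FALSE)
  im <- array(Im(cross), d)
  num <- abs(colSums(im))
  den <- colSums(abs(im))
  out <- ifelse(den == 0, NA_real_, num / pmax(den, .Machine$double.xmin))
  if (length(d) > 2) out <- array(out, d[-1])
  out
}

#' Average per-sample WPLI into fixed-width time windows
#'
#' Arithmetic mean of per-sample WPLI over consecutive bins (10 ms by
#' default) covering `window_range` (default 50-200 ms, i.e. 15 bins).
#' Undefined samples are excluded from the mean; a bin is undefined only if
#' all its samples are. Errors if the bin edges do not align with the
#' sample grid.
#'
#' @param w numeric matrix frequencies x samples of per-sample WPLI
#' @param time sample times in ms (length = ncol(w))
#' @param window_range analysis interval in ms, half-open
#' @param width bin width in ms
#' @return list with `wpli` (frequencies x bins), `window_starts` (ms) and
#'   `width`
#' @export
window_average <- function(w, time, window_range = c(50, 200), width = 10) {
  stopifnot(is.matrix(w), length(time) == ncol(w), width > 0)
  span <- window_range[2] - window_range[1]
  nb <- span / width
  if (abs(nb - round(nb)) > 1e-9)
    stop("window_range is not a whole number of bins", call. = FALSE)
  nb <- round(nb)
  dt <- stats::median(diff(time))
  edges <- window_range[1] + width * 0:nb
  if (any(abs((edges - time[1]) / dt - round((edges - time[1]) / dt)) > 1e-6))
    stop("window grid is not aligned to the sample grid", call. = FALSE)
  out <- matrix(NA_real_, nrow(w), nb)
  for (b in seq_len(nb)) {
    idx <- which(time >= edges[b] & time < edges[b + 1])
    if (length(idx) == 0)
      stop("window grid is not aligned to the sample grid", call. = FALSE)
    seg <- w[, idx, drop = FALSE]
    m <- rowMeans(seg, na.rm = TRUE)
    m[rowSums(!is.na(seg)) == 0] <- NA_real_
    out[, b] <- m
  }
  list(wpli = out, window_starts = edges[-(nb + 1)], width = width)
}

#' Windowed WPLI map for a set of ROI pairs
#'
#' Convenience wrapper chaining [cross_spectrum()], [wpli()] and
#' [window_average()] for every requested pair, producing the per-cell
#' synchrony container used by the group statistics.
#'
#' @param tf a `tf_cube`
#' @param pairs list of character pairs (default: all unordered ROI pairs)
#' @param window_range,width passed to [window_average()]
#' @param meta named list of cell metadata (subject, condition, stimulus)
#' @return object of class `sync_map`: `wpli` array pairs x freqs x bins,
#'   `pairs`, `freqs`, `window_starts`, `width`, `meta`
#' @export
sync_map <- function(tf, pairs = NULL, window_range = c(50, 200), width = 10,
                     meta = list()) {
  stopifnot(inherits(tf, "tf_cube"))
  if (is.null(pairs)) {
    cmb <- utils::combn(tf$rois, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  nb <- round((window_range[2] - window_range[1]) / width)
  arr <- array(NA_real_, c(length(pairs), length(tf$freqs), nb))
  ws <- NULL
  for (i in seq_along(pairs)) {
    w <- wpli(cross_spectrum(tf, pairs[[i]]))
    wa <- window_average(w, tf$time, window_range, width)
    arr[i, , ] <- wa$wpli
    ws <- wa$window_starts
  }
  structure(list(wpli = arr,
                 pairs = vapply(pairs, paste, character(1), collapse = "--"),
                 freqs = tf$freqs, window_starts = ws, width = width,
                 meta = meta),
            class = "sync_map")
}

#' Convert a sync map to a long-format data frame
#'
#' One row per pair x frequency x window, with any cell metadata repeated
#' as leading columns; the standard export format.
#'
#' @param x a `sync_map`
#' @return data.frame with columns pair, frequency, window_start, wpli and
#'   the metadata columns
#' @export
sync_map_to_df <- function(x) {
  stopifnot(inherits(x, "sync_map"))
  g <- expand.grid(pair = x$pairs, frequency = x$freqs,
                   window_start = x$window_starts,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$wpli <- as.vector(x$wpli)
  for (nm in rev(names(x$meta))) g[[nm]] <- x$meta[[nm]]
  g[, c(names(x$meta), "pair", "frequency", "window_start", "wpli")]
}
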