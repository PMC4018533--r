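#' Frequency grid for the wavelet transform
#'
#' Arithmetic grid of center frequencies; the defaults (8-80 Hz in 3 Hz
#' steps) give 25 frequencies. The number of wavelet cycles grows linearly
#' with frequency, `cycles(f) = f / cycles_divisor`; with the default
#' divisor 7 the cycle counts at the grid endpoints are 8/7 = 1.14 and
#' 80/7 = 11.43, i.e. 1.1 and 11.4 at display precision.
#'
#' @param start,stop grid endpoints in Hz
#' @param step grid step in Hz; (stop - start) must be divisible by step
#' @param cycles_divisor divisor of the linear cycle schedule
#' @return an object of class `frequency_grid` with elements `freqs` and
#'   `cycles`
#' @export
frequency_grid <- function(start = 8, stop = 80, step = 3,
                           cycles_divisor = 7) {
  stopifnot(start <= stop, step > 0, cycles_divisor > 0)
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9)
    stop("(stop - start) is not divisible by step: grid is ambiguous",
         call. = FALSE)
  freqs <- start + step * 0:round(k)
  structure(list(freqs = freqs, cycles = freqs / cycles_divisor,
                 start = start, stop = stop, step = step,
                 cycles_divisor = cycles_divisor),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d frequencies, %g-%g Hz step %g; cycles %.1f-%.1f\n",
              length(x$freqs), x$start, x$stop, x$step,
              min(x$cycles), max(x$cycles)))
  invisible(x)
}

#' Complex Morlet wavelet
#'
#' Complex exponential under a Gaussian envelope with `cycles` cycles:
#' sigma_t = cycles / (2*pi*f). Sampled over +/- 3.5 sigma_t and normalized
#' to unit L2 energy. Only the phase of the coefficients enters the WPLI,
#' so the amplitude normalization does not affect synchrony estimates.
#'
#' @param f center frequency in Hz
#' @param srate sampling rate in Hz
#' @param cycles number of cycles in the Gaussian envelope
#' @return complex vector of odd length (peak at the center sample); the
#'   attribute `half_support` gives the one-sided support in samples
#' @export
morlet_wavelet <- function(f, srate, cycles) {
  stopifnot(f > 0, cycles > 0)
  sigma_t <- cycles / (2 * pi * f)
  hs <- max(1L, ceiling(3.5 * sigma_t * srate))
  t <- (-hs:hs) / srate
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w <- w / sqrt(sum(Mod(w)^2))
  attr(w, "half_support") <- hs
  w
}

#' Continuous Morlet wavelet transform of epoched data
#'
#' Convolves every trial x ROI trace with a complex Morlet wavelet at each
#' grid frequency (zero-padded FFT convolution, output aligned to the input
#' time axis). The Gaussian envelope is symmetric, so convolution with the
#' wavelet equals correlation with it and a pure cosine at a grid frequency
#' yields coefficients whose phase advances at + 2*pi*f per second. Samples
#' within one wavelet half-support of either epoch edge are flagged as
#' boundary-affected per frequency.
#'
#' @param epochs an [epoch_array()]
#' @param grid a [frequency_grid()]
#' @param time_range optional interval in ms; only coefficients inside it
#'   are stored (the convolution always uses the full epoch), keeping the
#'   memory footprint of large cubes bounded
#' @return an object of class `tf_cube`: complex `coef` array of
#'   trials x ROIs x frequencies x samples, `freqs`, `time`, `rois`,
#'   `srate`, and a frequencies x samples logical `boundary` matrix
#' @export
morlet_transform <- function(epochs, grid, time_range = NULL) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(grid, "frequency_grid"))
  if (max(grid$freqs) >= epochs$srate / 2)
    stop("grid contains frequencies at or above the Nyquist frequency",
         call. = FALSE)
  d <- dim(epochs$data)
  ntr <- d[1]; nroi <- d[2]; ns <- d[3]
  nf <- length(grid$freqs)

  keep <- seq_len(ns)
  if (!is.null(time_range))
    keep <- which(epochs$time >= time_range[1] & epochs$time < time_range[2])
  if (length(keep) == 0) stop("time_range contains no samples", call. = FALSE)

  # trace matrix: samples x (trials*ROIs)
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), ns, ntr * nroi)

  coef <- array(complex(1), c(ntr, nroi, nf, length(keep)))
  boundary <- matrix(FALSE, nf, length(keep))
  for (j in seq_len(nf)) {
    w <- morlet_wavelet(grid$freqs[j], epochs$srate, grid$cycles[j])
    hs <- attr(w, "half_support")
    if (length(w) > ns)
      stop("epoch shorter than the wavelet support at ",
           grid$freqs[j], " Hz", call. = FALSE)
    nfft <- stats::nextn(ns + length(w) - 1, 2)
    wf <- stats::fft(c(w, complex(real = rep(0, nfft - length(w)))))
    xf <- stats::mvfft(rbind(x, matrix(0, nfft - ns, ntr * nroi)))
    full <- stats::mvfft(xf * wf, inverse = TRUE) / nfft
    cj <- full[(hs + 1):(hs + ns), , drop = FALSE]   # center of 'full' conv
    cj <- cj[keep, , drop = FALSE]
    coef[, , j, ] <- aperm(array(cj, c(length(keep), ntr, nroi)), c(2, 3, 1))
    edge <- seq_len(ns) <= hs | seq_len(ns) > ns - hs
    boundary[j, ] <- edge[keep]
  }

  structure(list(coef = coef, freqs = grid$freqs, time = epochs$time[keep],
                 rois = epochs$rois, srate = epochs$srate,
                 boundary = boundary, trials = epochs$trials,
                 subject = epochs$subject),
            class = "tf_cube")
}

#' @export
print.tf_cube <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("<tf_cube> %d trials x %d ROIs x %d freqs x %d samples\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
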