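#' Bartlett-Hanning window
#'
#' Coefficients of the modified Bartlett-Hanning window,
#' `w(x) = 0.62 - 0.48*|x| + 0.38*cos(2*pi*x)` for `x` in `[-1/2, 1/2]`.
#'
#' @param n Window length (number of taps).
#' @return Numeric vector of length `n`.
#' @export
barthann_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  x <- (seq_len(n) - 1) / (n - 1) - 0.5
  0.62 - 0.48 * abs(x) + 0.38 * cos(2 * pi * x)
}

.bank_notes <- new.env(parent = emptyenv())

# 60 Hz notch: 2nd-order Butterworth band-stop, 55-65 Hz at fs = 500
notch_filter <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- signal::butter(2, c(55, 65) / 250, type = "stop")
    memo
  }
})

#' Remove 60 Hz line noise
#'
#' Applies the designed IIR notch (2nd-order Butterworth band-stop, 10 Hz
#' stop band centred on 60 Hz) zero-phase to a signal sampled at 500 Hz:
#' the squared magnitude response -- what forward-backward filtering
#' applies -- is imposed in the frequency domain over odd-reflection
#' padding, so edge transients stay outside the returned segment and all
#' trials of an epoch stack are filtered in one pass.
#'
#' @param x Numeric vector, or matrix with one signal per row.
#' @param fs Sampling rate; must be 500.
#' @return Filtered signal, same shape as `x`.
#' @export
notch_60 <- function(x, fs = 500) {
  if (fs != 500) stop("notch_60 expects fs = 500, got ", fs)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stop("notch_60: signal contains non-finite samples")
  n <- ncol(x)
  p <- min(500L, n - 1L)
  xp <- cbind(2 * x[, rep(1, p), drop = FALSE] - x[, (p + 1):2, drop = FALSE],
              x,
              2 * x[, rep(n, p), drop = FALSE] - x[, (n - 1):(n - p), drop = FALSE])
  np <- ncol(xp)
  nfft <- stats::nextn(np + 1000, 2)
  H2 <- notch_h2(nfft, fs)
  X <- stats::mvfft(rbind(t(xp), matrix(0, nfft - np, nrow(x))))
  y <- Re(stats::mvfft(X * H2, inverse = TRUE)) / nfft
  out <- t(y[(p + 1):(p + n), , drop = FALSE])
  if (vec) drop(out) else out
}

# |H(e^{iw})|^2 of the notch at the FFT bin frequencies, cached per length
notch_h2 <- local({
  memo <- list()
  function(nfft, fs) {
    key <- as.character(nfft)
    if (is.null(memo[[key]])) {
      flt <- notch_filter()
      w <- 2 * pi * (0:(nfft - 1)) / nfft
      z <- exp(-1i * w)
      H <- outer(z, 0:(length(flt$b) - 1), "^") %*% flt$b /
        (outer(z, 0:(length(flt$a) - 1), "^") %*% flt$a)
      memo[[key]] <<- as.numeric(abs(H)^2)
    }
    memo[[key]]
  }
})

#' Trim filter edge artifacts from an epoch
#'
#' Removes `trim_s` seconds (default 100 ms) from both ends of an epoch,
#' discarding samples contaminated by convolution edge effects.
#'
#' @param x Numeric vector, or matrix with one epoch per row.
#' @param fs Sampling rate in Hz.
#' @param trim_s Seconds removed from each end.
#' @return Trimmed signal; a 1500-sample epoch at 500 Hz becomes 1400 samples.
#' @export
trim_edges <- function(x, fs = 500, trim_s = 0.1) {
  k <- round(trim_s * fs)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n <= 2 * k) {
    stop("epoch of ", n, " samples too short to trim ", k,
         " samples from each end")
  }
  if (is.matrix(x)) x[, (k + 1):(n - k), drop = FALSE] else x[(k + 1):(n - k)]
}

#' Design a Bartlett-Hanning band-pass FIR filter
#'
#' Linear-phase FIR band-pass of the given order, windowed with the
#' Bartlett-Hanning window.
#'
#' @param f_lo,f_hi Pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (number of taps minus one).
#' @return Numeric vector of `order + 1` filter coefficients.
#' @export
design_fir_bandpass <- function(f_lo, f_hi, fs = 500, order = 1000) {
  nyq <- fs / 2
  if (f_lo <= 0 || f_hi >= nyq || f_lo >= f_hi) {
    stop("band [", f_lo, ", ", f_hi, "] Hz outside (0, ", nyq, ") Hz")
  }
  key <- paste(f_lo, f_hi, fs, order, sep = "|")
  if (is.null(.fir_cache[[key]])) {
    .fir_cache[[key]] <- as.numeric(
      signal::fir1(order, c(f_lo, f_hi) / nyq, type = "pass",
                   window = barthann_window(order + 1)))
  }
  .fir_cache[[key]]
}

.fir_cache <- new.env(parent = emptyenv())

#' Zero-phase FIR filtering
#'
#' Filters one or more signals (columns of `x`) with a symmetric
#' (linear-phase) FIR filter via FFT convolution with odd reflection
#' padding and exact group-delay compensation, so filtered features stay
#' aligned to word onset.
#'
#' @param x Numeric vector, or matrix with one signal per column.
#' @param h FIR coefficients (odd length, symmetric).
#' @return Filtered signal, same shape as `x`.
#' @export
filter_zerophase <- function(x, h) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x); m <- length(h); half <- (m - 1) %/% 2
  p <- min(half + 1L, n - 1L)
  xp <- rbind(2 * x[rep(1, p), , drop = FALSE] - x[(p + 1):2, , drop = FALSE],
              x,
              2 * x[rep(n, p), , drop = FALSE] - x[(n - 1):(n - p), , drop = FALSE])
  np <- nrow(xp)
  nfft <- stats::nextn(np + m - 1, 2)
  H <- stats::fft(c(h, rep(0, nfft - m)))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  out <- y[(p + half + 1):(p + half + n), , drop = FALSE]
  if (vec) drop(out) else out
}

#' Band-pass filter bank
#'
#' Filters a signal through the six canonical Bartlett-Hanning band-pass
#' filters (or any supplied set of bands), applied zero-phase. Band-pass
#' filtering before power estimation confines each band's power estimate to
#' its own range and limits 1/f leakage from lower frequencies.
#'
#' @param x Numeric vector, or matrix with one signal per row.
#' @param bands Named list of [band_definition]s; default [filter_bands()].
#' @param fs Sampling rate in Hz.
#' @param order FIR order.
#' @return Named list with one filtered signal (same shape as `x`) per band.
#' @export
bandpass_bank <- function(x, bands = filter_bands(), fs = 500, order = 1000) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < 2 * order && !isTRUE(.bank_notes$short_warned)) {
    message("bandpass_bank: signal length ", n, " < 2 x filter order ",
            order, "; reflection padding in use (noted once per session)")
    .bank_notes$short_warned <- TRUE
  }
  xs <- if (is.matrix(x)) t(x) else matrix(x, ncol = 1)  # samples x signals
  # all bands share the filter order, hence one padded forward FFT
  m <- order + 1L; half <- order %/% 2
  ns <- nrow(xs)
  p <- min(half + 1L, ns - 1L)
  xp <- rbind(2 * xs[rep(1, p), , drop = FALSE] - xs[(p + 1):2, , drop = FALSE],
              xs,
              2 * xs[rep(ns, p), , drop = FALSE] - xs[(ns - 1):(ns - p), , drop = FALSE])
  np <- nrow(xp)
  nfft <- stats::nextn(np + m - 1, 2)
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - np, ncol(xp))))
  out <- lapply(bands, function(b) {
    key <- paste("H", b$f_lo, b$f_hi, fs, order, nfft, sep = "|")
    if (is.null(.fir_cache[[key]])) {
      h <- design_fir_bandpass(b$f_lo, b$f_hi, fs = fs, order = order)
      .fir_cache[[key]] <- stats::fft(c(h, rep(0, nfft - m)))
    }
    y <- Re(stats::mvfft(X * .fir_cache[[key]], inverse = TRUE)) / nfft
    y <- y[(p + half + 1):(p + half + ns), , drop = FALSE]
    if (is.matrix(x)) t(y) else drop(y)
  })
  names(out) <- names(bands)
  out
}

#' Resample a signal to 500 Hz
#'
#' Downsamples by polyphase resampling after an explicit zero-phase FIR
#' anti-aliasing low-pass (cut-off 0.9 x 250 Hz). Upsampling is refused:
#' content above the original Nyquist frequency cannot be recovered, and the
#' high-gamma analysis range must reflect measured activity.
#'
#' @param x Numeric vector, or matrix with one signal per row.
#' @param fs_in Input sampling rate in Hz (integer-valued, >= 500).
#' @return Signal at 500 Hz with length `round(n * 500 / fs_in)` per trace.
#' @export
resample_to_500 <- function(x, fs_in) {
  if (fs_in < 500) {
    stop("fs_in = ", fs_in, " < 500 Hz: refusing to upsample")
  }
  if (fs_in == 500) return(x)
  if (abs(fs_in - round(fs_in)) > 1e-9) {
    stop("fs_in must be integer-valued, got ", fs_in)
  }
  if (is.matrix(x)) return(t(apply(x, 1, resample_to_500, fs_in = fs_in)))
  fs_in <- as.integer(round(fs_in))
  g <- gcd_int(500L, fs_in)
  h <- design_fir_bandpass_low(0.9 * 250, fs_in, order = 400)
  xf <- filter_zerophase(x, h)
  y <- as.numeric(signal::resample(xf, 500L %/% g, fs_in %/% g))
  n_out <- round(length(x) * 500 / fs_in)
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(y[length(y)], n_out - length(y)))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# low-pass companion of design_fir_bandpass, used for anti-aliasing
design_fir_bandpass_low <- function(f_hi, fs, order = 400) {
  as.numeric(signal::fir1(order, f_hi / (fs / 2), type = "low",
                          window = barthann_window(order + 1)))
}
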