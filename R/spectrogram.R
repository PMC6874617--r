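#' @title Time-frequency decomposition of event-locked epochs
#' @description
#' Epochs are converted to spectrograms with 2-Hz frequency resolution by
#' sliding a 500 ms window in 50 ms steps along each band-pass-filtered
#' trace and reading the window periodogram at the 2-Hz lines covered by
#' that band. Log power is z-scored within each frequency bin across the
#' windows of the epoch (population mean and variance over the epoch), so
#' every trial spectrogram is dimensionless and amplitude-invariant; two
#' time bins are clipped from either end afterwards to drop residual edge
#' effects. A canonical 3000 ms epoch (1500 samples) trimmed to 1400 samples
#' yields 47 windows, 43 after clipping.
#' @name spectrogram
NULL

window_starts <- function(n, win, step) {
  if (n < win) stop("signal of ", n, " samples shorter than one window (", win, ")")
  seq(0L, n - win, by = step)  # 0-based; final partial window discarded
}

# Periodogram power of every sliding window at selected 2-Hz lines, for all
# trials at once. yf: samples x trials matrix (one band-filtered trace per
# column); bins: lower-edge labels (Hz) of the wanted 2-Hz lines.
# Returns array [bin, window, trial].
window_band_power <- function(yf, bins, fs = 500, win = 250, step = 25) {
  n <- nrow(yf); nt <- ncol(yf)
  starts <- window_starts(n, win, step)
  nw <- length(starts)
  idx <- as.vector(outer(seq_len(win), starts, "+"))  # win x nw, 1-based
  W <- matrix(yf[idx + rep((seq_len(nt) - 1L) * n, each = win * nw)],
              nrow = win)
  k <- bins * win / fs          # DFT line index for each 2-Hz bin
  ang <- 2 * pi * outer(k, 0:(win - 1)) / win
  P <- (cos(ang) %*% W)^2 + (sin(ang) %*% W)^2
  array(P, c(length(bins), nw, nt))
}

# Full spectrogram stack from band-filtered traces.
# band_signals: named list (one entry per filter band) of samples x trials
# matrices. Returns list(values = array [trial, window, bin] pre-clip,
# freq_bins, n_zero_var).
spectrogram_core <- function(band_signals, bands, fs = 500, win = 250,
                             step = 25) {
  pieces <- lapply(names(bands), function(nm) {
    bins <- band_bin_edges(bands[[nm]])
    list(bins = bins,
         power = window_band_power(band_signals[[nm]], bins, fs, win, step))
  })
  freq_bins <- unlist(lapply(pieces, `[[`, "bins"))
  o <- order(freq_bins)
  P <- do.call(function(...) abind1(...), lapply(pieces, `[[`, "power"))
  P <- P[o, , , drop = FALSE]
  freq_bins <- freq_bins[o]
  nb <- dim(P)[1]; nw <- dim(P)[2]; nt <- dim(P)[3]
  # guard offset per trial, then log and z-score every frequency row across
  # the epoch's windows (population SD); vectorised over trials
  eps <- vapply(seq_len(nt), function(j) 1e-12 * stats::median(P[, , j]), 0)
  L <- log(sweep(P, 3, eps, "+"))
  M <- matrix(aperm(L, c(2, 1, 3)), nrow = nw)     # nw x (nb*nt)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = nw)
  sd_pop <- sqrt(colMeans(Mc^2))
  zero <- sd_pop <= 0
  n_zero <- sum(zero)
  sd_pop[zero] <- 1
  Zc <- Mc / rep(sd_pop, each = nw)
  Zc[, zero] <- 0
  Z <- aperm(array(Zc, c(nw, nb, nt)), c(3, 1, 2)) # trial x window x bin
  list(values = Z, freq_bins = freq_bins, n_zero_var = n_zero)
}

abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0, c(sum(vapply(xs, function(x) dim(x)[1], 0L)), d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

window_centers_ms <- function(n, fs = 500, win = 250, step = 25,
                              offset_ms = 100) {
  (window_starts(n, win, step) + win / 2) / fs * 1000 + offset_ms
}

#' Spectrogram of a single epoch
#'
#' Computes the z-scored log-power spectrogram of one epoch from its
#' band-pass-filtered traces. Each frequency bin is z-scored across the
#' epoch's windows using the within-epoch mean and (population) variance,
#' then `clip` time bins are removed from each end.
#'
#' @param band_signals Named list of numeric vectors, one trimmed filtered
#'   trace per filter band (names matching `bands`).
#' @param bands Named list of [band_definition]s; default [filter_bands()].
#' @param fs Sampling rate in Hz.
#' @param clip Time bins clipped from each end after z-scoring (default 2;
#'   use 0 to inspect the raw normalized spectrogram).
#' @param trial_index Trial label carried on the result.
#' @return Object of class `trial_spectrogram`: `values`
#'   (time bin x frequency bin), `time_bins` (window centres, ms from epoch
#'   start), `freq_bins` (2-Hz bin lower edges, Hz), `trial_index`.
#' @export
epoch_spectrogram <- function(band_signals, bands = filter_bands(), fs = 500,
                              clip = 2, trial_index = 1L) {
  stopifnot(is.list(band_signals),
            all(names(bands) %in% names(band_signals)))
  lens <- vapply(band_signals[names(bands)], length, 0L)
  if (length(unique(lens)) != 1) stop("band signals have unequal lengths")
  mats <- lapply(band_signals[names(bands)], function(v) matrix(v, ncol = 1))
  win <- round(0.5 * fs); step <- round(0.05 * fs)
  core <- spectrogram_core(mats, bands, fs, win, step)
  if (core$n_zero_var > 0) {
    warning(core$n_zero_var,
            " frequency bin(s) had zero within-epoch variance; z-scores set to 0")
  }
  tb <- window_centers_ms(lens[1], fs, win, step)
  vals <- core$values[1, , , drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(core$freq_bins))
  keep <- clip_indices(nrow(vals), clip)
  structure(list(values = vals[keep, , drop = FALSE],
                 time_bins = tb[keep], freq_bins = core$freq_bins,
                 trial_index = trial_index),
            class = "trial_spectrogram")
}

clip_indices <- function(nw, clip) {
  if (clip > 0) {
    if (nw <= 2 * clip) stop("cannot clip ", clip, " bins from each end of ",
                             nw, " time bins")
    (clip + 1):(nw - clip)
  } else seq_len(nw)
}

#' Average spectrograms across trials
#'
#' Element-wise arithmetic mean of z-scored trial spectrograms. Values may be
#' negative or positive; deviations from 0 are event-locked power changes
#' that survive trial averaging.
#'
#' @param trials List of `trial_spectrogram` objects with identical axes.
#' @param electrode_id Electrode label carried on the result.
#' @return Object of class `averaged_spectrogram`: `values`
#'   (time bin x frequency bin), `time_bins`, `freq_bins`, `n_trials`,
#'   `electrode_id`.
#' @export
trial_average <- function(trials, electrode_id = "E1") {
  stopifnot(length(trials) >= 1)
  t0 <- trials[[1]]
  for (tr in trials[-1]) {
    if (!isTRUE(all.equal(tr$time_bins, t0$time_bins)) ||
        !identical(tr$freq_bins, t0$freq_bins)) {
      stop("trial spectrograms have mismatched time/frequency axes")
    }
  }
  acc <- Reduce(`+`, lapply(trials, `[[`, "values"))
  structure(list(values = acc / length(trials), time_bins = t0$time_bins,
                 freq_bins = t0$freq_bins, n_trials = length(trials),
                 electrode_id = electrode_id),
            class = "averaged_spectrogram")
}

#' Mean band power change
#'
#' Averages a trial-averaged spectrogram over the 2-Hz bins of one frequency
#' band, yielding the band's power time course in z-units. A bin belongs to
#' band `[f_lo, f_hi]` iff its centre lies in `[f_lo, f_hi + 1)`.
#'
#' @param avg An `averaged_spectrogram`.
#' @param band A [band_definition].
#' @return Object of class `band_power_series`: `values` (one per time bin),
#'   `time_bins`, `band`, `electrode_id`.
#' @export
mean_band_power <- function(avg, band) {
  bins <- band_bin_edges(band)
  sel <- avg$freq_bins %in% bins
  if (!any(sel)) {
    stop("band '", band$name, "' covers no frequency bins of this spectrogram")
  }
  structure(list(values = rowMeans(avg$values[, sel, drop = FALSE]),
                 time_bins = avg$time_bins, band = band,
                 electrode_id = avg$electrode_id),
            class = "band_power_series")
}

#' Mean band power change for every canonical band
#'
#' @param avg An `averaged_spectrogram`.
#' @param bands Named list of [band_definition]s; default [canonical_bands()].
#' @return Named list of `band_power_series`.
#' @export
band_power_all <- function(avg, bands = canonical_bands()) {
  out <- lapply(bands, function(b) mean_band_power(avg, b))
  names(out) <- names(bands)
  out
}

#' Trial-averaged spectrogram of one electrode's epoch stack
#'
#' End-to-end spectral path for a single electrode: 60 Hz notch, 100 ms edge
#' trims, band-pass filter bank, per-trial z-scored spectrograms (all trials
#' processed in one vectorised pass), and trial averaging.
#'
#' @param X Numeric matrix, trials x samples (raw epochs at 500 Hz).
#' @param fs Sampling rate; must be 500.
#' @param bands Filter bands; default [filter_bands()].
#' @param clip Time bins clipped from each end.
#' @param electrode_id Label carried on the result.
#' @return An `averaged_spectrogram`.
#' @export
electrode_spectrogram <- function(X, fs = 500, bands = filter_bands(),
                                  clip = 2, electrode_id = "E1") {
  stopifnot(is.matrix(X))
  Xn <- notch_60(X, fs = fs)
  if (!is.matrix(Xn)) Xn <- matrix(Xn, nrow = 1)
  Xt <- trim_edges(Xn, fs = fs)
  filt <- lapply(bandpass_bank(Xt, bands = bands, fs = fs), t)  # samples x trials
  win <- round(0.5 * fs); step <- round(0.05 * fs)
  core <- spectrogram_core(filt, bands, fs, win, step)
  if (core$n_zero_var > 0) {
    warning(core$n_zero_var,
            " frequency bin(s) had zero within-epoch variance; z-scores set to 0")
  }
  keep <- clip_indices(dim(core$values)[2], clip)
  vals <- apply(core$values[, keep, , drop = FALSE], c(2, 3), mean)
  tb <- window_centers_ms(ncol(Xt), fs, win, step)[keep]
  structure(list(values = vals, time_bins = tb, freq_bins = core$freq_bins,
                 n_trials = nrow(X), electrode_id = electrode_id),
            class = "averaged_spectrogram")
}
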