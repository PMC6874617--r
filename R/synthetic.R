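#' @title Synthetic iEEG with the structure the method assumes
#' @description
#' The generator emulates the two electrode phenotypes the classifier
#' separates. Inactive electrodes are stationary colored (1/f) Gaussian
#' noise plus a 60 Hz line component. Active electrodes add two
#' stimulus-locked effects: a theta oscillation whose amplitude is
#' suppressed during word presentation (the low-frequency power decrease)
#' and band-limited 65-115 Hz noise whose amplitude rises during word
#' presentation (the broadband high-gamma increase). Envelopes use 100 ms
#' raised-cosine ramps to avoid spectral splatter, word onsets are jittered
#' per trial, and per-trial lognormal amplitude jitter keeps trial
#' averaging non-degenerate.
#' @name synthetic
NULL

#' Configuration of the synthetic study
#'
#' Defaults are the strong-effect study condition: 15 percent active
#' electrodes, doubling of high-gamma amplitude and halving of theta
#' amplitude during word presentation, theta at twice the background RMS.
#'
#' @param n_subjects,n_electrodes Subjects and electrodes per subject.
#' @param frac_active Probability that an electrode is active.
#' @param n_trials Word-presentation events per electrode.
#' @param fs Sampling rate (Hz).
#' @param noise_exponent Spectral exponent beta of the 1/f^beta background.
#' @param line_60hz_amp 60 Hz line amplitude (x background RMS).
#' @param theta_freq Theta frequency (Hz).
#' @param theta_amp Theta amplitude outside the word window (x background
#'   RMS).
#' @param theta_suppression Multiplier on theta amplitude inside the word
#'   window (< 1 suppresses).
#' @param gamma_band High-gamma band of the active effect (Hz).
#' @param gamma_amp Baseline amplitude of the band-limited gamma component
#'   (x background RMS).
#' @param gamma_gain Multiplier on gamma amplitude inside the word window
#'   (>= 1).
#' @param word_window_s Word presentation window relative to onset (s).
#' @param onset_jitter_s Uniform per-trial onset jitter half-width (s).
#' @param amp_jitter_sd SD of the lognormal per-trial amplitude jitter.
#' @param pre_s,post_s Epoch extent around onset (s); 0.7 + 2.3 s = 3000 ms.
#' @param seed Master seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10, n_electrodes = 100,
                         frac_active = 0.15, n_trials = 40, fs = 500,
                         noise_exponent = 1.0, line_60hz_amp = 0.5,
                         theta_freq = 6, theta_amp = 2,
                         theta_suppression = 0.5,
                         gamma_band = c(65, 115), gamma_amp = 0.5,
                         gamma_gain = 2, word_window_s = c(0, 1.6),
                         onset_jitter_s = 0.05, amp_jitter_sd = 0.2,
                         pre_s = 0.7, post_s = 2.3, seed = 0) {
  if (frac_active < 0 || frac_active > 1) stop("frac_active must be in [0, 1]")
  if (gamma_gain < 1) stop("gamma_gain must be >= 1")
  amps <- c(line_60hz_amp, theta_amp, gamma_amp)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (theta_suppression < 0) stop("theta_suppression must be >= 0")
  if (n_trials < 1 || n_electrodes < 1 || n_subjects < 1) {
    stop("n_subjects, n_electrodes and n_trials must be positive")
  }
  structure(as.list(environment()), class = "synth_config")
}

# raised-cosine gate: `lo` outside [t_on, t_off], `hi` inside, ramps of
# `ramp_s` seconds centred on the boundaries
effect_envelope <- function(n, fs, t_on, t_off, lo, hi, ramp_s = 0.1) {
  t <- (seq_len(n) - 1) / fs
  up <- pmin(pmax((t - (t_on - ramp_s / 2)) / ramp_s, 0), 1)
  down <- pmin(pmax(((t_off + ramp_s / 2) - t) / ramp_s, 0), 1)
  g <- (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * down))
  lo + (hi - lo) * g
}

# colored-noise trials by FFT shaping of white noise: one column per trial,
# spectral amplitude ~ f^(-beta/2), unit RMS per trial
colored_noise <- function(n, n_trials, fs, beta) {
  W <- matrix(stats::rnorm(n * n_trials), n, n_trials)
  f <- seq(0, fs - fs / n, by = fs / n)
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror to [0, fs/2]
  shape <- c(0, f[-1]^(-beta / 2))      # kill DC
  X <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE)) / n
  sweep(X, 2, sqrt(colMeans(X^2)), "/")
}

# band-limited white noise via FFT masking, unit RMS per trial
bandlimited_noise <- function(n, n_trials, fs, f_lo, f_hi) {
  W <- matrix(stats::rnorm(n * n_trials), n, n_trials)
  f <- seq(0, fs - fs / n, by = fs / n)
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mask <- as.numeric(f >= f_lo & f <= f_hi)
  X <- Re(stats::mvfft(stats::mvfft(W) * mask, inverse = TRUE)) / n
  sweep(X, 2, sqrt(colMeans(X^2)), "/")
}

#' Simulate one subject's epoch set
#'
#' Generates `n_electrodes` epoch stacks of `n_trials` epochs each, with a
#' known active/inactive label per electrode. Deterministic for a fixed
#' `subject_seed`.
#'
#' @param config A [synth_config()].
#' @param subject_seed Seed for this subject's randomness.
#' @param subject_id Subject identifier.
#' @return List: `epochs` (an [epoch_set()]) and `truth` (data frame with
#'   `subject_id`, `electrode_id`, `truth_label`).
#' @export
simulate_subject <- function(config, subject_seed = config$seed,
                             subject_id = "S1") {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  n <- round((cf$pre_s + cf$post_s) * cf$fs)
  with_seed(subject_seed, {
    active <- stats::rbinom(cf$n_electrodes, 1, cf$frac_active) == 1
    dat <- array(0, c(cf$n_electrodes, cf$n_trials, n))
    t <- (seq_len(n) - 1) / cf$fs
    for (e in seq_len(cf$n_electrodes)) {
      X <- colored_noise(n, cf$n_trials, cf$fs, cf$noise_exponent)
      phases <- stats::runif(cf$n_trials, 0, 2 * pi)
      for (w in seq_len(cf$n_trials)) {
        X[, w] <- X[, w] +
          cf$line_60hz_amp * sin(2 * pi * 60 * t + phases[w])
      }
      if (active[e]) {
        G <- bandlimited_noise(n, cf$n_trials, cf$fs, cf$gamma_band[1],
                               cf$gamma_band[2])
        jit <- stats::runif(cf$n_trials, -cf$onset_jitter_s,
                            cf$onset_jitter_s)
        a_th <- exp(stats::rnorm(cf$n_trials, 0, cf$amp_jitter_sd))
        a_ga <- exp(stats::rnorm(cf$n_trials, 0, cf$amp_jitter_sd))
        th_phase <- stats::runif(cf$n_trials, 0, 2 * pi)
        for (w in seq_len(cf$n_trials)) {
          t_on <- cf$pre_s + cf$word_window_s[1] + jit[w]
          t_off <- cf$pre_s + cf$word_window_s[2] + jit[w]
          env_th <- effect_envelope(n, cf$fs, t_on, t_off,
                                    lo = cf$theta_amp * a_th[w],
                                    hi = cf$theta_amp * cf$theta_suppression * a_th[w])
          env_ga <- effect_envelope(n, cf$fs, t_on, t_off,
                                    lo = cf$gamma_amp * a_ga[w],
                                    hi = cf$gamma_amp * cf$gamma_gain * a_ga[w])
          X[, w] <- X[, w] +
            env_th * sin(2 * pi * cf$theta_freq * t + th_phase[w]) +
            env_ga * G[, w]
        }
      }
      dat[e, , ] <- t(X)
    }
    truth <- data.frame(
      subject_id = subject_id,
      electrode_id = paste0("E", seq_len(cf$n_electrodes)),
      truth_label = ifelse(active, "active", "inactive"),
      stringsAsFactors = FALSE)
    list(epochs = epoch_set(dat, fs = cf$fs, t0_offset = cf$pre_s,
                            subject_id = subject_id,
                            electrode_ids = truth$electrode_id),
         truth = truth)
  })
}

#' Simulate a multi-subject dataset
#'
#' Per-subject seeds are derived deterministically from the master seed.
#'
#' @param config A [synth_config()].
#' @return List of [simulate_subject()] results, one per subject.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lapply(seq_len(config$n_subjects), function(k) {
    simulate_subject(config,
                     subject_seed = (config$seed * 1000 + k) %% 2147483647,
                     subject_id = sprintf("S%02d", k))
  })
}

#' Simulate feature-level mixture samples
#'
#' Draws electrodes directly in metric space from a two-component Gaussian
#' (1-D, or diagonal multivariate) with known membership, for direct tests
#' of the clustering and evaluation machinery.
#'
#' @param n Number of electrodes (>= 20).
#' @param frac_active Active-component probability.
#' @param mean_active,mean_inactive Component means (scalars or length-d).
#' @param sd_active,sd_inactive Component SDs (positive; scalars or
#'   length-d).
#' @param seed Seed.
#' @param feature_name Column name(s) for the feature matrix.
#' @return List: `features` (n x d matrix), `truth` (labels).
#' @export
simulate_metric_clusters <- function(n, frac_active = 0.15,
                                     mean_active = 3.0, mean_inactive = 1.0,
                                     sd_active = 0.8, sd_inactive = 0.4,
                                     seed = 0, feature_name = "feature") {
  if (n < 20) stop("need n >= 20")
  if (any(c(sd_active, sd_inactive) <= 0)) stop("component SDs must be > 0")
  d <- max(length(mean_active), length(mean_inactive))
  mean_active <- rep_len(mean_active, d); mean_inactive <- rep_len(mean_inactive, d)
  sd_active <- rep_len(sd_active, d); sd_inactive <- rep_len(sd_inactive, d)
  with_seed(seed, {
    act <- stats::rbinom(n, 1, frac_active) == 1
    X <- matrix(0, n, d)
    for (j in seq_len(d)) {
      X[, j] <- ifelse(act,
                       stats::rnorm(n, mean_active[j], sd_active[j]),
                       stats::rnorm(n, mean_inactive[j], sd_inactive[j]))
    }
    colnames(X) <- if (d == 1) feature_name else
      paste0(feature_name, "_", seq_len(d))
    list(features = X, truth = ifelse(act, "active", "inactive"))
  })
}
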