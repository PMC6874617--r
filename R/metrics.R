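#' @title Electrode-level spectral metrics
#' @description
#' Three interpretable metrics summarise each electrode's trial-averaged
#' band power time courses: induced power (total absolute deviation of the
#' z-scored band power), smoothness score (1-lag autocorrelation of the
#' theta band power), and gamma consistency (sorted absolute pairwise
#' correlations among the three gamma power time courses). Together they
#' contribute 11 features per electrode: 6 IP + 2 SS + 3 GC.
#' @name metrics
NULL

series_values <- function(x) {
  if (inherits(x, "band_power_series")) x$values else as.numeric(x)
}

#' Induced power
#'
#' Sum over time of the absolute mean band power change, `sum_t |S(t)|`.
#' Large values indicate sustained deviation of band power from the epoch
#' mean, the signature of a task-induced response.
#'
#' @param series A `band_power_series` or numeric vector (z-units).
#' @return Non-negative scalar.
#' @export
induced_power <- function(series) {
  v <- series_values(series)
  if (length(v) == 0) stop("induced_power: empty series")
  if (!all(is.finite(v))) stop("induced_power: non-finite values in series")
  sum(abs(v))
}

#' Lag-1 autocorrelation (lagged-copy estimator)
#'
#' Pearson correlation of a series with its 1-sample lagged copy,
#' `Corr(x[2:n], x[1:(n-1)])`. This is the "correlate with the lagged copy"
#' estimator, not the autocovariance-ratio estimator; the two differ at the
#' short series lengths used here, so the choice is fixed. Returns `NA`
#' when either slice has zero variance.
#'
#' @param x Numeric vector, length >= 3.
#' @return Scalar in [-1, 1], or `NA`.
#' @export
lag1_autocorr <- function(x) {
  n <- length(x)
  if (n < 3) stop("lag-1 autocorrelation needs a series of length >= 3")
  a <- x[-1]; b <- x[-n]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Smoothness score
#'
#' 1-lag autocorrelation of the mean band power change in the low-theta and
#' high-theta bands; values lie in [-1, 1]. Smooth, slowly varying power
#' time courses (expected for task-responsive theta) give values near 1;
#' uncorrelated noise gives values near 0. A zero-variance series yields
#' `NA` with a warning, and the electrode is excluded from SS-based
#' clustering downstream.
#'
#' @param series_theta_l,series_theta_h `band_power_series` or numeric
#'   vectors for the two theta bands.
#' @return Named numeric vector `c(ss_theta_l, ss_theta_h)`.
#' @export
smoothness_score <- function(series_theta_l, series_theta_h) {
  out <- c(ss_theta_l = lag1_autocorr(series_values(series_theta_l)),
           ss_theta_h = lag1_autocorr(series_values(series_theta_h)))
  if (anyNA(out)) {
    warning("smoothness score undefined for a zero-variance series")
  }
  out
}

#' Gamma consistency
#'
#' Absolute zero-lag Pearson correlations between the mean band power
#' changes of low gamma, high gamma 1 and high gamma 2, sorted in
#' descending order: `GC1 >= GC2 >= GC3`, each in [0, 1]. Broadband
#' task-induced gamma responses move the three gamma ranges together, so
#' active electrodes score high on all three pairs.
#'
#' @param series_gamma_l,series_gamma_h1,series_gamma_h2
#'   `band_power_series` or numeric vectors for the three gamma ranges.
#' @return Named numeric vector `c(gc_1, gc_2, gc_3)`, non-increasing.
#' @export
gamma_consistency <- function(series_gamma_l, series_gamma_h1,
                              series_gamma_h2) {
  xs <- list(series_values(series_gamma_l), series_values(series_gamma_h1),
             series_values(series_gamma_h2))
  lens <- vapply(xs, length, 0L)
  if (length(unique(lens)) != 1 || lens[1] < 3) {
    stop("gamma consistency needs three equal-length series of length >= 3")
  }
  if (any(vapply(xs, stats::sd, 0) == 0)) {
    warning("gamma consistency undefined for a zero-variance series")
    return(c(gc_1 = NA_real_, gc_2 = NA_real_, gc_3 = NA_real_))
  }
  cc <- abs(c(stats::cor(xs[[1]], xs[[2]]), stats::cor(xs[[1]], xs[[3]]),
              stats::cor(xs[[2]], xs[[3]])))
  stats::setNames(sort(cc, decreasing = TRUE), c("gc_1", "gc_2", "gc_3"))
}

#' Feature columns of the metric table
#' @return Character vector of the 11 metric feature column names.
#' @export
metric_feature_names <- function() {
  c("ip_theta_l", "ip_theta_h", "ip_alpha", "ip_beta", "ip_gamma_l",
    "ip_gamma_h", "ss_theta_l", "ss_theta_h", "gc_1", "gc_2", "gc_3")
}

#' Compute the per-electrode metric table
#'
#' Builds the 11-feature metric vector for every electrode from its mean
#' band power series. Induced power uses the six physiological bands (the
#' combined 65-115 Hz high-gamma, not its halves); smoothness uses the two
#' theta bands; gamma consistency uses low gamma and the two high-gamma
#' halves.
#'
#' @param series_by_electrode Named list (one entry per electrode); each
#'   entry a named list of `band_power_series`/numeric vectors containing at
#'   least `theta_l`, `theta_h`, `alpha`, `beta`, `gamma_l`, `gamma_h`,
#'   `gamma_h1`, `gamma_h2`.
#' @param subject_id Subject identifier for all rows.
#' @param truth_label Optional per-electrode ground-truth labels
#'   (`"active"`/`"inactive"`).
#' @return Data frame with columns `subject_id`, `electrode_id`, the 11
#'   features, and `truth_label` when supplied. Undefined SS/GC values are
#'   `NA`.
#' @export
compute_metric_table <- function(series_by_electrode, subject_id = "S1",
                                 truth_label = NULL) {
  need <- c("theta_l", "theta_h", "alpha", "beta", "gamma_l", "gamma_h",
            "gamma_h1", "gamma_h2")
  ids <- names(series_by_electrode)
  if (is.null(ids)) ids <- paste0("E", seq_along(series_by_electrode))
  rows <- lapply(seq_along(series_by_electrode), function(i) {
    s <- series_by_electrode[[i]]
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      stop("electrode '", ids[i], "': missing band series: ",
           paste(miss, collapse = ", "))
    }
    ip <- vapply(c("theta_l", "theta_h", "alpha", "beta", "gamma_l",
                   "gamma_h"),
                 function(b) induced_power(s[[b]]), 0)
    ss <- suppressWarnings(smoothness_score(s$theta_l, s$theta_h))
    gc <- suppressWarnings(gamma_consistency(s$gamma_l, s$gamma_h1,
                                             s$gamma_h2))
    c(ip, ss, gc)
  })
  feat <- do.call(rbind, rows)
  colnames(feat) <- metric_feature_names()
  out <- data.frame(subject_id = subject_id, electrode_id = ids,
                    feat, stringsAsFactors = FALSE, row.names = NULL)
  n_undef <- sum(!stats::complete.cases(feat))
  if (n_undef > 0) {
    message("compute_metric_table: ", n_undef,
            " electrode(s) with undefined SS/GC values (flagged as NA)")
  }
  if (!is.null(truth_label)) out$truth_label <- as.character(truth_label)
  out
}

#' Write / read a metric table
#'
#' Tab-separated serialisation of the metric table.
#'
#' @param x Metric table data frame.
#' @param path File path.
#' @return `read_metric_table` returns the data frame; `write_metric_table`
#'   returns `path` invisibly.
#' @export
write_metric_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
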