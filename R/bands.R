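#' Frequency band definition
#'
#' A band is a closed interval `[f_lo, f_hi]` in Hz with a name. The canonical
#' analysis bands span 2-115 Hz; arbitrary bands below the Nyquist frequency
#' are accepted so that the machinery can be reused at other sampling rates.
#'
#' @param name Band name (string).
#' @param f_lo,f_hi Band edges in Hz, inclusive; `0 < f_lo < f_hi`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_lo >= f_hi) {
    stop("invalid band '", name, "': need 0 < f_lo < f_hi, got [",
         f_lo, ", ", f_hi, "]")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: [%g, %g] Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Canonical frequency bands
#'
#' The eight analysis ranges: low theta (2-5 Hz), high theta (6-9 Hz),
#' alpha (10-15 Hz), beta (16-25 Hz), low gamma (36-55 Hz), high gamma
#' (65-115 Hz) and its two halves high gamma 1 (65-89 Hz) and high gamma 2
#' (90-115 Hz). The split high-gamma ranges exist to support the gamma
#' consistency metric; induced power uses the combined 65-115 Hz band.
#'
#' @return Named list of [band_definition] objects.
#' @export
canonical_bands <- function() {
  list(
    theta_l  = band_definition("theta_l",  2,  5),
    theta_h  = band_definition("theta_h",  6,  9),
    alpha    = band_definition("alpha",   10, 15),
    beta     = band_definition("beta",    16, 25),
    gamma_l  = band_definition("gamma_l", 36, 55),
    gamma_h  = band_definition("gamma_h", 65, 115),
    gamma_h1 = band_definition("gamma_h1", 65, 89),
    gamma_h2 = band_definition("gamma_h2", 90, 115)
  )
}

#' The six band-pass filter bands
#'
#' The filter bank runs on low theta, high theta, alpha, beta, low gamma and
#' the combined high gamma band; high gamma 1/2 are read out of the combined
#' high-gamma trace at the spectrogram stage.
#'
#' @return Named list of [band_definition] objects.
#' @export
filter_bands <- function() {
  canonical_bands()[c("theta_l", "theta_h", "alpha", "beta",
                      "gamma_l", "gamma_h")]
}

# 2-Hz frequency bins, labeled by their lower edge (even Hz). A bin
# [f, f+2) belongs to band [lo, hi] iff its center f+1 lies in [lo, hi+1),
# which makes the printed integer band edges exhaustive and non-overlapping.
band_bin_edges <- function(band) {
  f <- seq(2L * ceiling((band$f_lo - 1) / 2), 2L * floor(band$f_hi / 2),
           by = 2L)
  f[f >= 2]  # DC and the 0-2 Hz line are never analysed
}

# which canonical filter band covers each analysis band's bins
parent_filter_band <- function(band_name) {
  switch(band_name,
         gamma_h1 = "gamma_h",
         gamma_h2 = "gamma_h",
         band_name)
}
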