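# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, sharing no code with the package internals they check.

naive_induced_power <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s
}

naive_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

naive_lag1 <- function(x) naive_pearson(x[-1], x[-length(x)])

naive_gc <- function(a, b, c) {
  v <- c(abs(naive_pearson(a, b)), abs(naive_pearson(a, c)),
         abs(naive_pearson(b, c)))
  sort(v, decreasing = TRUE)
}

naive_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (n - 1))
}

# all-pairs AUC with ties counted one half
naive_auc <- function(scores, truth) {
  pos <- scores[truth == "active"]
  neg <- scores[truth == "inactive"]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(scores, truth) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- truth == "active"
  tpr <- vapply(ths, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(ths, function(t) mean(scores[!pos] >= t), 0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# per-window periodogram + log + z-score spectrogram, naive loops
naive_spectrogram <- function(band_signals, bands, fs = 500, clip = 2) {
  win <- round(0.5 * fs); step <- round(0.05 * fs)
  cols <- list()
  for (nm in names(bands)) {
    b <- bands[[nm]]
    f <- seq(2 * ceiling((b$f_lo - 1) / 2), 2 * floor(b$f_hi / 2), by = 2)
    f <- f[f >= 2]
    for (fb in f) cols[[length(cols) + 1]] <- list(f = fb, sig = band_signals[[nm]])
  }
  cols <- cols[order(vapply(cols, `[[`, 0, "f"))]
  n <- length(cols[[1]]$sig)
  starts <- seq(0, n - win, by = step)
  P <- matrix(0, length(starts), length(cols))
  for (j in seq_along(cols)) {
    k <- cols[[j]]$f * win / fs
    for (w in seq_along(starts)) {
      seg <- cols[[j]]$sig[(starts[w] + 1):(starts[w] + win)]
      re <- sum(seg * cos(2 * pi * k * (0:(win - 1)) / win))
      im <- sum(seg * sin(2 * pi * k * (0:(win - 1)) / win))
      P[w, j] <- re^2 + im^2
    }
  }
  eps <- 1e-12 * stats::median(P)
  L <- log(P + eps)
  Z <- L
  for (j in seq_len(ncol(L))) {
    m <- mean(L[, j])
    s <- sqrt(mean((L[, j] - m)^2))
    Z[, j] <- if (s > 0) (L[, j] - m) / s else 0
  }
  if (clip > 0) Z <- Z[(clip + 1):(nrow(Z) - clip), , drop = FALSE]
  Z
}

# adjacency enumeration over grid positions (row-major contact order)
naive_montage_count <- function(n_rows, n_cols) {
  cnt <- 0
  pos <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols))
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(pos))) {
      if (i < j && abs(pos$r[i] - pos$r[j]) + abs(pos$c[i] - pos$c[j]) == 1) {
        cnt <- cnt + 1
      }
    }
  }
  cnt
}

# magnitude response of an FIR filter at frequency f (Hz)
fir_gain <- function(h, f, fs = 500) {
  k <- seq_along(h) - 1
  abs(sum(h * exp(-1i * 2 * pi * f * k / fs)))
}

rms <- function(x) sqrt(mean(x^2))
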