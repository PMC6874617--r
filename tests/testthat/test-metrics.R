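test_that("induced power equals the absolute-sum oracle and its exact cases", {
  expect_equal(induced_power(rep(0, 43)), 0)
  expect_equal(induced_power(rep(0.5, 43)), 21.5)
  expect_error(induced_power(numeric(0)), "empty")

  set.seed(101)
  for (i in 1:1000) {
    x <- rnorm(sample(5:60, 1))
    expect_equal(induced_power(x), naive_induced_power(x),
                 tolerance = 1e-10)
    expect_identical(induced_power(x), induced_power(-x))
  }
})

test_that("smoothness score is the lag-1 Pearson autocorrelation", {
  alt <- rep(c(1, -1), 21)
  expect_equal(lag1_autocorr(alt), naive_lag1(alt), tolerance = 1e-10)
  expect_lt(lag1_autocorr(alt), -0.99)

  ramp <- 0:42
  expect_equal(lag1_autocorr(ramp), naive_lag1(ramp), tolerance = 1e-10)
  expect_gt(lag1_autocorr(ramp), 0.99)

  set.seed(102)
  for (i in 1:1000) {
    x <- rnorm(43)
    expect_equal(lag1_autocorr(x), naive_lag1(x), tolerance = 1e-10)
  }

  ss <- smoothness_score(sin(1:43 / 4), cos(1:43 / 4))
  expect_true(all(ss >= -1 & ss <= 1))
  expect_named(ss, c("ss_theta_l", "ss_theta_h"))
  expect_warning(out <- smoothness_score(rep(1, 43), rnorm(43)),
                 "zero-variance")
  expect_true(is.na(out["ss_theta_l"]))
})

test_that("the smoothness score of white noise is centred near zero", {
  set.seed(103)
  vals <- replicate(1000, lag1_autocorr(rnorm(43)))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("gamma consistency is the sorted absolute pairwise correlation", {
  set.seed(104)
  x <- rnorm(43); z <- rnorm(43)

  expect_equal(unname(gamma_consistency(x, x, x)), c(1, 1, 1))
  expect_equal(unname(gamma_consistency(x, -x, x)), c(1, 1, 1))

  gc <- gamma_consistency(x, x, z)
  expect_equal(unname(gc[1]), 1)
  expect_equal(unname(gc[2]), unname(gc[3]))
  expect_equal(unname(gc[2]), abs(naive_pearson(x, z)), tolerance = 1e-10)

  for (i in 1:1000) {
    a <- rnorm(30); b <- rnorm(30); cc <- rnorm(30)
    expect_equal(unname(gamma_consistency(a, b, cc)), naive_gc(a, b, cc),
                 tolerance = 1e-10)
  }

  expect_warning(out <- gamma_consistency(rep(2, 43), x, z), "zero-variance")
  expect_true(all(is.na(out)))
  expect_error(gamma_consistency(rnorm(10), rnorm(9), rnorm(10)),
               "equal-length")
})

test_that("SS and GC are scale-invariant while IP scales by |k|", {
  set.seed(105)
  x <- rnorm(43); y <- rnorm(43); z <- rnorm(43)
  for (k in c(-3, 0.2, 40)) {
    expect_equal(lag1_autocorr(k * x), lag1_autocorr(x), tolerance = 1e-12)
    expect_equal(gamma_consistency(k * x, y, z), gamma_consistency(x, y, z),
                 tolerance = 1e-12)
    expect_equal(induced_power(k * x), abs(k) * induced_power(x),
                 tolerance = 1e-12)
  }
})

test_that("the metric table carries 11 features with valid ranges", {
  set.seed(106)
  mk <- function() {
    s <- lapply(1:8, function(i) rnorm(43))
    names(s) <- c("theta_l", "theta_h", "alpha", "beta", "gamma_l",
                  "gamma_h", "gamma_h1", "gamma_h2")
    s
  }
  tab <- compute_metric_table(stats::setNames(lapply(1:6, function(i) mk()),
                                              paste0("E", 1:6)),
                              subject_id = "S9")
  expect_equal(nrow(tab), 6)
  expect_equal(metric_feature_names(),
               setdiff(names(tab), c("subject_id", "electrode_id")))
  expect_length(metric_feature_names(), 11)
  ip_cols <- grep("^ip_", names(tab), value = TRUE)
  expect_true(all(as.matrix(tab[, ip_cols]) >= 0))
  expect_true(all(abs(as.matrix(tab[, c("ss_theta_l", "ss_theta_h")])) <= 1))
  gcs <- as.matrix(tab[, c("gc_1", "gc_2", "gc_3")])
  expect_true(all(gcs >= 0 & gcs <= 1))
  expect_true(all(gcs[, 1] >= gcs[, 2] & gcs[, 2] >= gcs[, 3]))
})

test_that("all-zero series give zero IP and flagged SS/GC", {
  z <- lapply(1:8, function(i) rep(0, 43))
  names(z) <- c("theta_l", "theta_h", "alpha", "beta", "gamma_l",
                "gamma_h", "gamma_h1", "gamma_h2")
  expect_message(tab <- compute_metric_table(list(E1 = z)), "undefined")
  expect_true(all(tab[, grep("^ip_", names(tab))] == 0))
  expect_true(all(is.na(tab[, c("ss_theta_l", "ss_theta_h",
                                "gc_1", "gc_2", "gc_3")])))
})

test_that("a missing band is reported by name", {
  s <- lapply(1:7, function(i) rnorm(43))
  names(s) <- c("theta_l", "theta_h", "alpha", "beta", "gamma_l",
                "gamma_h", "gamma_h1")
  expect_error(compute_metric_table(list(E1 = s)), "gamma_h2")
})

test_that("induced high-gamma power separates simulated active electrodes", {
  cfg <- synth_config(n_electrodes = 40, frac_active = 0.3, n_trials = 8,
                      seed = 2)
  sub <- simulate_subject(cfg, subject_seed = 77)
  an <- analyze_epochs(sub$epochs, sub$truth)
  ip <- an$metrics$ip_gamma_h
  act <- an$metrics$truth_label == "active"
  expect_gt(median(ip[act]), median(ip[!act]))
})

test_that("metric tables round-trip through TSV", {
  set.seed(107)
  s <- lapply(1:8, function(i) rnorm(43))
  names(s) <- c("theta_l", "theta_h", "alpha", "beta", "gamma_l",
                "gamma_h", "gamma_h1", "gamma_h2")
  tab <- compute_metric_table(list(E1 = s, E2 = s), truth_label = c("active", "inactive"))
  p <- tempfile(fileext = ".tsv")
  write_metric_table(tab, p)
  back <- read_metric_table(p)
  expect_equal(back$ip_gamma_h, tab$ip_gamma_h, tolerance = 1e-12)
  expect_equal(back$truth_label, tab$truth_label)
})
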