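well_separated <- function(n = 2000, seed = 0) {
  simulate_metric_clusters(n, frac_active = 0.15, mean_active = 8,
                           mean_inactive = 1, sd_active = 0.8,
                           sd_inactive = 0.4, seed = seed)
}

test_that("the mixture fit recovers a known 1-D two-component structure", {
  sim <- simulate_metric_clusters(10000, seed = 1)
  fit <- fit_gmm(sim$features, seed = 1)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_lt(abs(min(fit$weights) - 0.15), 0.02)
  expect_equal(fit$active_component, which.min(fit$weights))
  # the active component sits at the higher mean
  expect_gt(fit$means[fit$active_component, 1],
            fit$means[3 - fit$active_component, 1])
  acc <- mean(fit$labels == sim$truth)
  expect_gt(acc, 0.95)
})

test_that("mixture fits are deterministic for a fixed seed", {
  sim <- well_separated(seed = 3)
  f1 <- fit_gmm(sim$features, seed = 42)
  f2 <- fit_gmm(sim$features, seed = 42)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$posteriors, f2$posteriors)
  expect_identical(f1$labels, f2$labels)
})

test_that("EM log-likelihood is non-decreasing along the trace", {
  sim <- simulate_metric_clusters(3000, seed = 4)
  fit <- fit_gmm(sim$features, seed = 0)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$log_likelihood)))
  expect_true(fit$converged)
})

test_that("degenerate and tied cases follow the stated policies", {
  expect_error(fit_gmm(matrix(1, 50, 1), seed = 0), "identical")
  expect_error(fit_gmm(matrix(rnorm(10), 10, 1), seed = 0), "at least 20")
  expect_error(fit_gmm(matrix(c(rnorm(39), NA), 40, 1), seed = 0),
               "non-finite")

  means <- rbind(c(2, 0), c(5, 0))
  expect_warning(k <- select_active_component(c(0.5, 0.5), means), "tied")
  expect_equal(k, 2)
  expect_equal(select_active_component(c(0.3, 0.7), means), 1)
})

test_that("active labels are invariant to component relabeling across seeds", {
  sim <- well_separated(seed = 6)
  labs <- lapply(c(1, 2, 3, 99), function(s) fit_gmm(sim$features, s)$labels)
  for (l in labs[-1]) expect_identical(l, labs[[1]])
})

test_that("label accuracy is non-decreasing in cluster separation", {
  acc_at <- function(delta) {
    mean(vapply(1:20, function(r) {
      sim <- simulate_metric_clusters(500, mean_active = 1 + delta,
                                      mean_inactive = 1, sd_active = 0.5,
                                      sd_inactive = 0.5, seed = 1000 * delta + r)
      mean(fit_gmm(sim$features, seed = r)$labels == sim$truth)
    }, 0))
  }
  accs <- vapply(c(2, 4, 8), acc_at, 0)
  expect_true(all(diff(accs) >= -0.005))
})

test_that("the fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  sim <- simulate_metric_clusters(5000, seed = 8)
  fit <- fit_gmm(sim$features, seed = 0)
  ref <- mclust::Mclust(sim$features[, 1], G = 2, modelNames = "V",
                        verbose = FALSE)
  expect_lt(abs(min(fit$weights) - min(ref$parameters$pro)), 0.02)
  expect_equal(sort(fit$means[, 1]), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.05)
})

test_that("frozen models transfer to new data with calibrated posteriors", {
  sim <- well_separated(seed = 9)
  fit <- fit_gmm(sim$features, seed = 0)
  act <- fit$active_component

  at_mean <- matrix(fit$means[act, 1], dimnames = list(NULL, "feature"))
  expect_gt(apply_model(fit, at_mean)$posteriors, 0.99)

  empty <- matrix(numeric(0), 0, 1, dimnames = list(NULL, "feature"))
  out <- apply_model(fit, empty)
  expect_length(out$posteriors, 0)
  expect_length(out$labels, 0)

  bad <- matrix(1, 1, 1, dimnames = list(NULL, "wrong_name"))
  expect_error(apply_model(fit, bad), "do not match")

  # symmetric equal-weight model: the midpoint scores exactly 0.5
  sym <- fit
  sym$weights <- c(0.5, 0.5)
  sym$means <- rbind(-2, 2)
  sym$covariances <- array(1, c(2, 1, 1))
  sym$active_component <- 2L
  mid <- matrix(0, dimnames = list(NULL, "feature"))
  expect_equal(apply_model(sym, mid)$posteriors, 0.5, tolerance = 1e-12)
})

test_that("posterior labels respect the 0.5 decision threshold", {
  sim <- simulate_metric_clusters(2000, seed = 10)
  fit <- fit_gmm(sim$features, seed = 0)
  expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
  expect_identical(fit$labels, ifelse(fit$posteriors >= 0.5,
                                      "active", "inactive"))
})

test_that("repeated clustering is reproducible and stable when separable", {
  sim <- well_separated(seed = 12)
  rc1 <- repeat_clustering(sim$features, n_runs = 8, truth = sim$truth)
  rc2 <- repeat_clustering(sim$features, n_runs = 8, truth = sim$truth)
  expect_identical(rc1$labels, rc2$labels)
  expect_identical(rc1$summary, rc2$summary)
  expect_gte(rc1$agreement, 0.99)

  one <- repeat_clustering(sim$features, n_runs = 1, truth = sim$truth)
  expect_equal(one$agreement, 1)
  expect_true(all(one$summary$sd == 0))
})

test_that("PCA on the correlation matrix has the analytic limiting behaviour", {
  set.seed(13)
  # independent standardised features: flat spectrum
  Xi <- matrix(rnorm(20000 * 11), ncol = 11)
  p1 <- pca_correlation(Xi)
  expect_lt(max(abs(p1$explained_fraction - 1 / 11)), 0.012)

  # one feature duplicated: rank-1 correlation
  x <- rnorm(500)
  Xd <- matrix(rep(x, 11), ncol = 11)
  Xd <- Xd + matrix(rnorm(length(Xd), sd = 1e-8), ncol = 11)
  p2 <- pca_correlation(Xd)
  expect_gt(p2$explained_fraction[1], 0.999)

  # structural invariants
  X <- matrix(rnorm(300 * 5), ncol = 5)
  p3 <- pca_correlation(X)
  expect_equal(sum(p3$explained_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p3$explained_fraction) <= 1e-12))
  expect_equal(unname(crossprod(p3$loadings)), diag(5), tolerance = 1e-9)

  Xc <- cbind(X, constant = 1)
  colnames(Xc) <- c(paste0("f", 1:5), "is_const")
  expect_error(pca_correlation(Xc), "is_const")
})

test_that("the thresholding baseline applies a strict cutoff on the sd", {
  expect_identical(threshold_baseline(list(rep(0.3, 43))), "inactive")

  # a series whose sample sd is exactly 0.05: strictly-greater rule keeps it
  x005 <- c(-0.05, -0.05, 0, 0.05, 0.05)
  expect_identical(sd(x005), 0.05)
  expect_identical(threshold_baseline(list(x005)), "inactive")
  expect_identical(threshold_baseline(list(x005 * 1.01)), "active")

  # strictness independent of representation: threshold == sd never fires
  set.seed(14)
  y <- rnorm(43)
  expect_identical(threshold_baseline(list(y), threshold = sd(y)),
                   "inactive")

  series <- lapply(1:1000, function(i) rnorm(43, sd = runif(1, 0.01, 0.12)))
  got <- threshold_baseline(series)
  want <- ifelse(vapply(series, naive_sd, 0) > 0.05, "active", "inactive")
  expect_identical(got, want)

  m <- rbind(a = rep(0, 10), b = c(rep(0, 9), 1))
  expect_identical(unname(threshold_baseline(m)), c("inactive", "active"))
})

test_that("mixture models survive JSON serialisation", {
  sim <- well_separated(seed = 15)
  fit <- fit_gmm(sim$features, seed = 0)
  p <- tempfile(fileext = ".json")
  write_gmm_model(fit, p)
  back <- read_gmm_model(p)
  probe <- matrix(seq(0, 8, length.out = 20), dimnames = list(NULL, "feature"))
  expect_equal(apply_model(back, probe)$posteriors,
               apply_model(fit, probe)$posteriors, tolerance = 1e-12)
})
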