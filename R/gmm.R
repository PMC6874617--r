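#' @title Two-component Gaussian mixture classification of electrodes
#' @description
#' Electrodes pooled across subjects are clustered in metric space with a
#' two-component Gaussian mixture fitted by EM. Because far fewer electrodes
#' respond to the task than not (typically 10-30 percent), the component
#' with the smaller mixture weight is designated the active cluster. The EM
#' fit is seeded (k-means++ initialisation), so a repeat protocol over many
#' seeds quantifies the robustness of the clusters.
#' @name clustering
NULL

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, ncol = 1)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  features
}

#' Drop rows with undefined metric values
#'
#' Electrodes whose SS/GC metrics were undefined (zero-variance series)
#' carry `NA` sentinels; they are excluded from clustering and counted.
#'
#' @param features Matrix or data frame of feature values.
#' @return The matrix restricted to complete rows, with attribute
#'   `n_excluded` giving the number of dropped rows.
#' @export
drop_undefined_rows <- function(features) {
  X <- as_feature_matrix(features)
  ok <- stats::complete.cases(X)
  if (any(!ok)) {
    message("excluding ", sum(!ok), " row(s) with undefined metric values")
  }
  structure(X[ok, , drop = FALSE], n_excluded = sum(!ok), kept = which(ok))
}

# k-means++ seeding for two centers, then one nearest-center assignment
kmeanspp_init <- function(X) {
  n <- nrow(X)
  c1 <- X[sample.int(n, 1), , drop = FALSE]
  d2 <- rowSums((X - c1[rep(1, n), , drop = FALSE])^2)
  if (sum(d2) <= 0) stop("degenerate features: all rows identical")
  c2 <- X[sample.int(n, 1, prob = d2), , drop = FALSE]
  d2b <- rowSums((X - c2[rep(1, n), , drop = FALSE])^2)
  ifelse(d2 <= d2b, 1L, 2L)
}

# log N(x | mu, Sigma) for all rows of X; Sigma already floored
log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  if (d == 1) {
    return(stats::dnorm(X[, 1], mu, sqrt(Sigma[1, 1]), log = TRUE))
  }
  R <- chol(Sigma)
  z <- forwardsolve(t(R), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

cov_floored <- function(X, w, floor_diag) {
  mu <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * w, Xc) / sum(w)
  if (ncol(X) > 1) {
    # scalar-variance components only in 1-D; full covariance otherwise
    S <- S + diag(floor_diag, ncol(X))
  } else {
    S <- matrix(max(S[1, 1], floor_diag), 1, 1)
  }
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    S <- S + diag(max(floor_diag, 1e-8) * 10, ncol(X))
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) stop("EM degenerate: singular component covariance")
  }
  list(mu = mu, Sigma = S)
}

#' Choose the active mixture component
#'
#' The component with the smaller mixture weight is the active cluster. On a
#' weight tie (difference below `tol`), the component with the larger mean
#' on the first feature is chosen and a warning is raised.
#'
#' @param weights Two mixture weights.
#' @param means 2 x d matrix of component means.
#' @param tol Tie tolerance on the weight difference.
#' @return Component index (1 or 2).
#' @export
select_active_component <- function(weights, means, tol = 1e-6) {
  if (abs(weights[1] - weights[2]) < tol) {
    warning("mixture weights tied; choosing the component with the larger ",
            "mean on the first feature")
    return(which.max(means[, 1]))
  }
  which.min(weights)
}

#' Fit a two-component Gaussian mixture to electrode features
#'
#' EM fit with k-means++ initialisation (seeded), full covariances for
#' multivariate features and scalar variances in 1-D. The smaller-weight
#' component is designated active; per-electrode posteriors of that
#' component give the continuous activity score, and hard labels use a 0.5
#' posterior threshold.
#'
#' @param features Numeric matrix/data frame (rows = electrodes) or vector
#'   for a single feature. No missing values (see [drop_undefined_rows()]).
#' @param seed Integer seed controlling the initialisation.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param var_floor Variance floor as a fraction of each feature's variance.
#' @return Object of class `gmm_result`: `weights`, `means` (2 x d),
#'   `covariances` (2 x d x d), `active_component`, `posteriors` (active
#'   component probability per row), `labels` (`"active"`/`"inactive"`),
#'   `log_likelihood`, `loglik_trace`, `feature_names`, `seed`,
#'   `n_iter`, `converged`.
#' @export
fit_gmm <- function(features, seed = 0, max_iter = 500, tol = 1e-6,
                    var_floor = 1e-8) {
  X <- as_feature_matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (n < 20) stop("fit_gmm needs at least 20 rows, got ", n)
  if (!all(is.finite(X))) {
    stop("fit_gmm: non-finite feature values; drop undefined rows first")
  }
  fvar <- apply(X, 2, stats::var)
  if (all(fvar <= 0)) stop("degenerate features: all rows identical")
  floor_diag <- var_floor * mean(fvar)

  assign0 <- with_seed(seed, kmeanspp_init(X))
  resp <- cbind(as.numeric(assign0 == 1L), as.numeric(assign0 == 2L))
  # soften empty/singleton groups
  resp <- (resp + 1e-3) / rowSums(resp + 1e-3)

  w <- colMeans(resp)
  comp <- lapply(1:2, function(k) cov_floored(X, resp[, k], floor_diag))
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lp <- vapply(1:2, function(k) {
      log(w[k]) + log_dmvnorm(X, comp[[k]]$mu, comp[[k]]$Sigma)
    }, numeric(n))
    m <- pmax(lp[, 1], lp[, 2])
    lse <- m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lp - lse)
    w <- colMeans(resp)
    comp <- lapply(1:2, function(k) cov_floored(X, resp[, k], floor_diag))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  means <- do.call(rbind, lapply(comp, `[[`, "mu"))
  covs <- array(0, c(2, d, d))
  for (k in 1:2) covs[k, , ] <- comp[[k]]$Sigma
  active <- select_active_component(w, means)
  post <- resp[, active]
  structure(list(weights = w, means = means, covariances = covs,
                 active_component = active, posteriors = post,
                 labels = ifelse(post >= 0.5, "active", "inactive"),
                 log_likelihood = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 feature_names = colnames(X), seed = seed,
                 n_iter = it, converged = converged),
            class = "gmm_result")
}

#' @export
print.gmm_result <- function(x, ...) {
  cat(sprintf(
    "<gmm_result> %d features, weights %.3f/%.3f, active = component %d (%.1f%% labelled active)\n",
    length(x$feature_names), x$weights[1], x$weights[2], x$active_component,
    100 * mean(x$labels == "active")))
  invisible(x)
}

#' Apply a fitted mixture to new electrodes
#'
#' Computes the posterior probability of the active component under frozen
#' mixture parameters and thresholds it into labels. Used for
#' leave-one-subject-out validation and for transferring a population model
#' to new recordings.
#'
#' @param model A `gmm_result` (or a read-back serialised model).
#' @param new_features Feature matrix with the same columns the model was
#'   fitted on.
#' @param threshold Posterior decision threshold.
#' @return List with `posteriors` and `labels`.
#' @export
apply_model <- function(model, new_features, threshold = 0.5) {
  X <- as_feature_matrix(new_features)
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature columns (", paste(colnames(X), collapse = ", "),
         ") do not match the model's (",
         paste(model$feature_names, collapse = ", "), ")")
  }
  if (nrow(X) == 0) {
    return(list(posteriors = numeric(0), labels = character(0)))
  }
  n <- nrow(X)
  lp <- vapply(1:2, function(k) {
    log(model$weights[k]) +
      log_dmvnorm(X, model$means[k, ], as.matrix(model$covariances[k, , ]))
  }, numeric(n))
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = 1)
  m <- pmax(lp[, 1], lp[, 2])
  post <- exp(lp[, model$active_component] - m) /
    (exp(lp[, 1] - m) + exp(lp[, 2] - m))
  list(posteriors = post,
       labels = ifelse(post >= threshold, "active", "inactive"))
}

#' Repeat the mixture clustering across seeds
#'
#' Runs [fit_gmm()] under `n_runs` distinct seeds and reports across-run
#' label agreement; with ground truth supplied, also the per-run
#' sensitivity/specificity/AUC and their mean and standard deviation (the
#' robustness protocol behind "mean (SD)" result tables).
#'
#' @param features Feature matrix (rows = electrodes).
#' @param n_runs Number of runs.
#' @param seeds Integer seeds, one per run; default `0:(n_runs-1)`.
#' @param truth Optional ground-truth labels (`"active"`/`"inactive"`).
#' @return Object of class `repeat_clustering`: `runs` (list of
#'   `gmm_result`), `labels` (electrodes x runs matrix), `agreement` (mean
#'   pairwise across-run label agreement), `seeds`, and with truth a
#'   `per_run` data frame plus `summary` (mean/sd rows).
#' @export
repeat_clustering <- function(features, n_runs = 100, seeds = NULL,
                              truth = NULL) {
  stopifnot(n_runs >= 1)
  if (is.null(seeds)) seeds <- seq.int(0L, n_runs - 1L)
  stopifnot(length(seeds) == n_runs)
  runs <- lapply(seeds, function(s) fit_gmm(features, seed = s))
  labels <- vapply(runs, `[[`, character(nrow(as_feature_matrix(features))),
                   "labels")
  labels <- matrix(labels, ncol = n_runs)
  agreement <- if (n_runs == 1) 1 else {
    ca <- rowSums(labels == "active")
    mean((ca * (ca - 1) + (n_runs - ca) * (n_runs - ca - 1)) /
           (n_runs * (n_runs - 1)))
  }
  out <- list(runs = runs, labels = labels, agreement = agreement,
              seeds = seeds)
  if (!is.null(truth)) {
    per_run <- do.call(rbind, lapply(seq_len(n_runs), function(i) {
      cm <- confusion_metrics(labels[, i], truth)
      auc <- auc_score(runs[[i]]$posteriors, truth)
      data.frame(run = i, seed = seeds[i], sensitivity = cm$sensitivity,
                 specificity = cm$specificity, auc = auc)
    }))
    smean <- colMeans(per_run[, c("sensitivity", "specificity", "auc")],
                      na.rm = TRUE)
    ssd <- if (n_runs == 1) c(sensitivity = 0, specificity = 0, auc = 0) else
      apply(per_run[, c("sensitivity", "specificity", "auc")], 2, stats::sd,
            na.rm = TRUE)
    out$per_run <- per_run
    out$summary <- data.frame(metric = names(smean), mean = as.numeric(smean),
                              sd = as.numeric(ssd))
  }
  class(out) <- "repeat_clustering"
  out
}

#' Principal component analysis of the metric correlation matrix
#'
#' Eigendecomposition of the feature correlation matrix; component scores
#' are the standardised features projected on the loadings. Each component
#' score vector can be clustered with [fit_gmm()] like any single feature.
#'
#' @param features Feature matrix (all 11 metric features, typically).
#' @return Object of class `pca_result`: `loadings` (d x d, orthonormal),
#'   `explained_fraction` (non-increasing, sums to 1), `scores`
#'   (n x d), `feature_names`.
#' @export
pca_correlation <- function(features) {
  X <- as_feature_matrix(features)
  if (nrow(X) < ncol(X) + 1) {
    stop("pca_correlation needs at least d + 1 = ", ncol(X) + 1, " rows")
  }
  if (!all(is.finite(X))) stop("pca_correlation: non-finite feature values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  C <- stats::cor(X)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  vals <- pmax(eg$values, 0)
  scores <- scale(X) %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(X)
  structure(list(loadings = V, explained_fraction = vals / sum(vals),
                 scores = scores, feature_names = colnames(X)),
            class = "pca_result")
}

#' Thresholding baseline classifier
#'
#' The initial filtering step of the semiautomatic reference approach: an
#' electrode is called active when the standard deviation across time of
#' its high-gamma mean band power change exceeds the threshold (strictly).
#'
#' @param series_list List of `band_power_series`/numeric vectors (one per
#'   electrode), or a numeric matrix electrodes x time bins.
#' @param threshold Standard-deviation threshold (default 0.05).
#' @return Character vector of labels, `"active"`/`"inactive"`.
#' @export
threshold_baseline <- function(series_list, threshold = 0.05) {
  if (is.matrix(series_list)) {
    sds <- apply(series_list, 1, stats::sd)
  } else {
    sds <- vapply(series_list, function(s) stats::sd(series_values(s)), 0)
  }
  ifelse(sds > threshold, "active", "inactive")
}

#' Serialise / load a fitted mixture model
#'
#' Portable JSON document holding weights, means, covariances, feature
#' names, the active component index and the seed, so a population model
#' can be applied to other recordings.
#'
#' @param model A `gmm_result`.
#' @param path File path.
#' @return `read_gmm_model` returns a `gmm_result`-compatible model (without
#'   per-electrode fields); `write_gmm_model` returns `path` invisibly.
#' @export
write_gmm_model <- function(model, path) {
  d <- length(model$feature_names)
  doc <- list(weights = model$weights,
              means = model$means,
              covariances = lapply(1:2, function(k)
                matrix(model$covariances[k, , ], d, d)),
              feature_names = model$feature_names,
              active_component = model$active_component,
              seed = model$seed,
              package_version = as.character(utils::packageVersion("ieegactive")))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gmm_model
#' @export
read_gmm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(doc$feature_names)
  covs <- array(0, c(2, d, d))
  for (k in 1:2) covs[k, , ] <- as.matrix(doc$covariances[[k]])
  structure(list(weights = as.numeric(doc$weights),
                 means = matrix(as.numeric(doc$means), 2, d),
                 covariances = covs,
                 active_component = as.integer(doc$active_component),
                 feature_names = as.character(doc$feature_names),
                 seed = doc$seed),
            class = "gmm_result")
}
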