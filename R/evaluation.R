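#' @title Classifier evaluation against ground truth
#' @description
#' Predicted labels and continuous activity scores are compared with
#' ground-truth active/inactive labels using sensitivity, specificity and
#' the rank-based area under the ROC curve, with a leave-one-subject-out
#' protocol for cross-subject generalisation and region-level summaries of
#' the anatomical distribution of active electrodes.
#' @name evaluation
NULL

as_label <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("active", "inactive"))
  if (length(bad)) stop("labels must be 'active'/'inactive'; got: ",
                        paste(bad, collapse = ", "))
  x
}

#' Sensitivity and specificity of predicted labels
#'
#' Sensitivity is the percentage of true-active electrodes labelled active
#' (`100 * TP / (TP + FN)`); specificity the percentage of true-inactive
#' electrodes labelled inactive (`100 * TN / (TN + FP)`). When the truth
#' contains a single class, the undefined rate is reported as `NA` with a
#' warning.
#'
#' @param pred,truth Label vectors (`"active"`/`"inactive"`), equal length.
#' @return List: `sensitivity`, `specificity` (percent), `n_active_truth`,
#'   `n_inactive_truth`.
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as_label(pred); truth <- as_label(truth)
  stopifnot(length(pred) == length(truth))
  pos <- truth == "active"
  n1 <- sum(pos); n0 <- sum(!pos)
  sens <- if (n1 == 0) NA_real_ else 100 * sum(pred[pos] == "active") / n1
  spec <- if (n0 == 0) NA_real_ else 100 * sum(pred[!pos] == "inactive") / n0
  if (n1 == 0 || n0 == 0) {
    warning("single-class ground truth: ",
            if (n1 == 0) "sensitivity" else "specificity", " undefined")
  }
  list(sensitivity = sens, specificity = spec,
       n_active_truth = n1, n_inactive_truth = n0)
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen true-active electrode outscores a
#' randomly chosen true-inactive one, with ties counted one half
#' (Mann-Whitney convention). Computed from mid-ranks; identical to the
#' all-pairs enumeration.
#'
#' @param scores Numeric activity scores (e.g. active-component posteriors).
#' @param truth Ground-truth labels (`"active"`/`"inactive"`).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, truth) {
  truth <- as_label(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- truth == "active"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: ground truth has one class")
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, fits the two-component mixture on all other subjects'
#' electrodes, applies the frozen model to the held-out subject, and scores
#' it against ground truth. The pooled summary gives mean (SD) across
#' subjects and the fraction of subjects whose AUC exceeds `auc_cutoff`.
#' Held-out subjects with single-class truth get `NA` for the undefined
#' rates and AUC.
#'
#' @param metric_table Metric table with `subject_id`, feature columns and
#'   `truth_label`.
#' @param feature_cols Feature column name(s) to cluster on.
#' @param seed Seed for every fold's mixture fit.
#' @param auc_cutoff AUC cutoff for the subject-level success fraction.
#' @param threshold Posterior decision threshold.
#' @return List: `per_subject` data frame (subject, n, sensitivity,
#'   specificity, auc), `summary` data frame (mean/sd per metric), and
#'   `frac_auc_above` (fraction of subjects with AUC > `auc_cutoff`).
#' @export
loso_cv <- function(metric_table, feature_cols = "ip_gamma_h", seed = 0,
                    auc_cutoff = 0.90, threshold = 0.5) {
  stopifnot(all(c("subject_id", "truth_label", feature_cols) %in%
                  names(metric_table)))
  subjects <- unique(metric_table$subject_id)
  if (length(subjects) < 2) stop("leave-one-subject-out needs >= 2 subjects")
  rows <- lapply(subjects, function(s) {
    hold <- metric_table$subject_id == s
    train <- as_feature_matrix(metric_table[!hold, feature_cols, drop = FALSE])
    test <- as_feature_matrix(metric_table[hold, feature_cols, drop = FALSE])
    model <- fit_gmm(train, seed = seed)
    pred <- apply_model(model, test, threshold = threshold)
    truth <- metric_table$truth_label[hold]
    cm <- suppressWarnings(confusion_metrics(pred$labels, truth))
    auc <- if (length(unique(truth)) < 2) NA_real_ else
      auc_score(pred$posteriors, truth)
    data.frame(subject_id = s, n = sum(hold), sensitivity = cm$sensitivity,
               specificity = cm$specificity, auc = auc,
               stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  vals <- per_subject[, c("sensitivity", "specificity", "auc")]
  summary <- data.frame(
    metric = names(vals),
    mean = vapply(vals, function(v) mean(v, na.rm = TRUE), 0),
    sd = vapply(vals, function(v) stats::sd(v, na.rm = TRUE), 0),
    row.names = NULL)
  list(per_subject = per_subject, summary = summary,
       frac_auc_above = mean(per_subject$auc > auc_cutoff, na.rm = TRUE),
       auc_cutoff = auc_cutoff)
}

#' Anatomical region summary of active electrodes
#'
#' Aggregates labels by region (and hemisphere when available), reports the
#' percentage of active electrodes per region, and flags the rows at or
#' above the given percentile of the per-region percentage distribution.
#' Regions with fewer than `min_electrodes` implanted electrodes (both
#' hemispheres combined) are excluded; electrodes without a region mapping
#' are dropped with a warning.
#'
#' @param labels Data frame with `subject_id`, `electrode_id`, `label`.
#' @param region_table Data frame with `subject_id`, `electrode_id`,
#'   `region` and optionally `hemisphere`.
#' @param min_electrodes Minimum electrodes per region.
#' @param percentile Flagging percentile (0-100) of the per-row percentage
#'   distribution (linear-interpolation estimator).
#' @return List: `summary` data frame (`region`, `hemisphere`,
#'   `n_electrodes`, `n_active`, `pct_active`, `selected`) and `cutoff`, the
#'   realised percentage cutoff.
#' @export
region_summary <- function(labels, region_table, min_electrodes = 40,
                           percentile = 85) {
  stopifnot(all(c("subject_id", "electrode_id", "label") %in% names(labels)),
            all(c("subject_id", "electrode_id", "region") %in%
                  names(region_table)))
  if (!"hemisphere" %in% names(region_table)) region_table$hemisphere <- "both"
  key <- function(d) paste(d$subject_id, d$electrode_id, sep = "\r")
  m <- match(key(labels), key(region_table))
  if (anyNA(m)) {
    warning(sum(is.na(m)), " electrode(s) without a region mapping dropped")
  }
  ok <- !is.na(m)
  df <- data.frame(region = region_table$region[m[ok]],
                   hemisphere = region_table$hemisphere[m[ok]],
                   active = labels$label[ok] == "active",
                   stringsAsFactors = FALSE)
  region_n <- tapply(rep(1L, nrow(df)), df$region, sum)
  keep_regions <- names(region_n)[region_n >= min_electrodes]
  df <- df[df$region %in% keep_regions, , drop = FALSE]
  if (nrow(df) == 0) {
    warning("no region with at least ", min_electrodes, " electrodes")
    return(list(summary = data.frame(region = character(),
                                     hemisphere = character(),
                                     n_electrodes = integer(),
                                     n_active = integer(),
                                     pct_active = numeric(),
                                     selected = logical()),
                cutoff = NA_real_))
  }
  agg <- stats::aggregate(active ~ region + hemisphere, data = df,
                          FUN = function(v) c(n = length(v), a = sum(v)))
  out <- data.frame(region = agg$region, hemisphere = agg$hemisphere,
                    n_electrodes = as.integer(agg$active[, "n"]),
                    n_active = as.integer(agg$active[, "a"]),
                    stringsAsFactors = FALSE)
  out$pct_active <- 100 * out$n_active / out$n_electrodes
  out <- out[order(-out$pct_active, out$region, out$hemisphere), ]
  rownames(out) <- NULL
  cutoff <- as.numeric(stats::quantile(out$pct_active, percentile / 100,
                                       type = 7))
  # a region is only highlighted if it actually contains active electrodes
  out$selected <- out$pct_active >= cutoff & out$n_active > 0
  list(summary = out, cutoff = cutoff)
}
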