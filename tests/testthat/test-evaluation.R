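test_that("sensitivity and specificity follow the confusion-table ratios", {
  truth <- rep(c("active", "inactive"), c(4, 6))
  cm <- confusion_metrics(truth, truth)
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100)
  expect_equal(cm$n_active_truth, 4)

  all_in <- confusion_metrics(rep("inactive", 10), truth)
  expect_equal(all_in$sensitivity, 0)
  expect_equal(all_in$specificity, 100)

  # TP = 9, FN = 1, TN = 85, FP = 5
  truth2 <- rep(c("active", "inactive"), c(10, 90))
  pred2 <- c(rep("active", 9), "inactive", rep("inactive", 85),
             rep("active", 5))
  cm2 <- confusion_metrics(pred2, truth2)
  expect_equal(cm2$sensitivity, 90)
  expect_equal(cm2$specificity, 100 * 85 / 90, tolerance = 1e-12)

  expect_warning(cm3 <- confusion_metrics(rep("active", 5),
                                          rep("active", 5)),
                 "specificity undefined")
  expect_true(is.na(cm3$specificity))
  expect_equal(cm3$sensitivity, 100)
})

test_that("confusion metrics are order-invariant and symmetric under label swap", {
  set.seed(31)
  truth <- sample(c("active", "inactive"), 60, replace = TRUE)
  pred <- sample(c("active", "inactive"), 60, replace = TRUE)
  o <- sample(60)
  a <- confusion_metrics(pred, truth)
  b <- confusion_metrics(pred[o], truth[o])
  expect_equal(a, b)

  flip <- function(x) ifelse(x == "active", "inactive", "active")
  sw <- confusion_metrics(flip(pred), flip(truth))
  expect_equal(sw$sensitivity, a$specificity)
  expect_equal(sw$specificity, a$sensitivity)
})

test_that("rank-based AUC equals the all-pairs oracle and both ROC constructions", {
  truth <- rep(c("active", "inactive"), c(5, 5))
  expect_equal(auc_score(c(6:10, 1:5), truth), 1.0)
  expect_equal(auc_score(rep(2, 10), truth), 0.5)
  expect_error(auc_score(1:5, rep("active", 5)), "one class")

  set.seed(32)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    truth_i <- c("active", "inactive",
                 sample(c("active", "inactive"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    a <- auc_score(scores, truth_i)
    expect_identical(a, naive_auc(scores, truth_i))
    expect_equal(a, trapezoid_auc(scores, truth_i), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  truth <- sample(c("active", "inactive"), 200, replace = TRUE)
  scores <- rnorm(200) + (truth == "active")
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c("inactive", "active"),
                                   direction = "<"))))
  expect_equal(auc_score(scores, truth), ref, tolerance = 1e-12)
})

test_that("leave-one-subject-out generalises across subjects from one population", {
  tabs <- lapply(1:5, function(k) {
    sim <- simulate_metric_clusters(200, frac_active = 0.15, mean_active = 3,
                                    mean_inactive = 1, sd_active = 0.8,
                                    sd_inactive = 0.4, seed = 500 + k,
                                    feature_name = "ip_gamma_h")
    data.frame(subject_id = sprintf("S%d", k),
               electrode_id = paste0("E", 1:200),
               ip_gamma_h = sim$features[, 1],
               truth_label = sim$truth, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  cv <- loso_cv(tab, "ip_gamma_h", seed = 0)
  expect_equal(nrow(cv$per_subject), 5)
  expect_true(all(cv$per_subject$auc >= 0.95))
  expect_equal(cv$frac_auc_above,
               mean(cv$per_subject$auc > 0.90, na.rm = TRUE))
  expect_equal(cv$summary$mean[cv$summary$metric == "auc"],
               mean(cv$per_subject$auc))
})

test_that("identical held-out subjects give identical fold reports", {
  sim <- simulate_metric_clusters(300, seed = 41, feature_name = "ip_gamma_h")
  tab <- rbind(
    data.frame(subject_id = "A", electrode_id = paste0("E", 1:300),
               ip_gamma_h = sim$features[, 1], truth_label = sim$truth),
    data.frame(subject_id = "B", electrode_id = paste0("E", 1:300),
               ip_gamma_h = sim$features[, 1], truth_label = sim$truth))
  cv <- loso_cv(tab, "ip_gamma_h", seed = 1)
  expect_equal(cv$per_subject$sensitivity[1], cv$per_subject$sensitivity[2])
  expect_equal(cv$per_subject$auc[1], cv$per_subject$auc[2])

  one <- tab[tab$subject_id == "A", ]
  expect_error(loso_cv(one, "ip_gamma_h"), ">= 2 subjects")
})

test_that("region summaries aggregate, filter and flag as specified", {
  # 10 regions with constructed counts; only >= 40-electrode regions qualify
  ns <- c(60, 50, 45, 80, 40, 55, 70, 44, 48, 39)
  act <- c(30, 5, 9, 8, 2, 11, 7, 22, 0, 39)
  labels <- do.call(rbind, lapply(1:10, function(r) {
    data.frame(subject_id = "S1",
               electrode_id = sprintf("R%d_E%d", r, seq_len(ns[r])),
               label = rep(c("active", "inactive"), c(act[r], ns[r] - act[r])),
               stringsAsFactors = FALSE)
  }))
  regions <- data.frame(subject_id = "S1", electrode_id = labels$electrode_id,
                        region = sub("_E.*", "", labels$electrode_id),
                        hemisphere = "left", stringsAsFactors = FALSE)
  rs <- region_summary(labels, regions)
  expect_equal(nrow(rs$summary), 9)            # R10 has 39 electrodes
  expect_false("R10" %in% rs$summary$region)

  pct <- 100 * act[1:9] / ns[1:9]
  expect_equal(sort(rs$summary$pct_active), sort(pct))
  expect_equal(rs$cutoff, as.numeric(quantile(pct, 0.85)))
  want_flagged <- sub("_E.*", "",
                      paste0("R", which(pct >= quantile(pct, 0.85)), "_E"))
  expect_setequal(rs$summary$region[rs$summary$selected], want_flagged)
})

test_that("region summary edge cases: unmapped electrodes and no active calls", {
  labels <- data.frame(subject_id = "S1",
                       electrode_id = paste0("E", 1:90),
                       label = "inactive", stringsAsFactors = FALSE)
  regions <- data.frame(subject_id = "S1", electrode_id = paste0("E", 1:80),
                        region = rep(c("A", "B"), each = 40),
                        stringsAsFactors = FALSE)
  expect_warning(rs <- region_summary(labels, regions), "without a region")
  expect_true(all(rs$summary$pct_active == 0))
  expect_false(any(rs$summary$selected))

  small <- data.frame(subject_id = "S1", electrode_id = paste0("E", 1:90),
                      region = paste0("tiny", 1:90), stringsAsFactors = FALSE)
  expect_warning(rs2 <- region_summary(labels, small), "at least 40")
  expect_equal(nrow(rs2$summary), 0)
})
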