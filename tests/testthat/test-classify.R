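separated_features <- function(n_a = 37, n_b = 40, gap = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n_a + n_b)),
    group = factor(rep(c("SWEDD", "PD"), c(n_a, n_b)), levels = c("SWEDD", "PD")),
    f1 = c(rnorm(n_a, -gap), rnorm(n_b, gap)),
    f2 = c(rnorm(n_a, -gap), rnorm(n_b, gap)))
}

test_that("well-separated classes reach 100% LOOCV accuracy over n folds", {
  feats <- separated_features()
  res <- loocv_linear_svm(feats)
  expect_equal(res$metrics$accuracy, 100)
  expect_equal(res$metrics$sensitivity, 100)
  expect_equal(res$metrics$specificity, 100)
  expect_equal(res$settings$n_folds, 77)
  expect_equal(nrow(res$folds), 77)
})

test_that("LOOCV predictions are deterministic and standardization-invariant", {
  feats <- separated_features(n_a = 10, n_b = 12, gap = 1.2, seed = 4)
  r1 <- loocv_linear_svm(feats)
  r2 <- loocv_linear_svm(feats)
  expect_identical(r1$folds$predicted, r2$folds$predicted)
  # positive rescaling of a feature column changes nothing after per-fold scaling
  feats_scaled <- dplyr::mutate(feats, f1 = f1 * 1000)
  r3 <- loocv_linear_svm(feats_scaled)
  expect_identical(r1$folds$predicted, r3$folds$predicted)
})

test_that("label-permuted features classify at chance level", {
  feats <- separated_features(seed = 2)
  set.seed(77)
  accs <- sapply(1:3, function(i) {
    shuffled <- feats
    shuffled$group <- sample(feats$group)
    loocv_linear_svm(shuffled)$metrics$accuracy
  })
  expect_true(all(accs >= 35 & accs <= 65))
})

test_that("confusion metrics reproduce the worked 37-vs-40 example exactly", {
  # 29 of 37 positives and 31 of 40 negatives correct
  truth <- rep(c("SWEDD", "PD"), c(37, 40))
  pred <- c(rep("SWEDD", 29), rep("PD", 8), rep("PD", 31), rep("SWEDD", 9))
  m <- confusion_metrics(pred, truth, positive_class = "SWEDD")
  expect_equal(m$tp, 29)
  expect_equal(m$fn, 8)
  expect_equal(m$tn, 31)
  expect_equal(m$fp, 9)
  expect_equal(m$sensitivity, 78.38)
  expect_equal(m$specificity, 77.50)
  expect_equal(m$accuracy, 77.92)
})

test_that("confusion metrics hit the trivial extremes", {
  truth <- rep(c("A", "B"), c(5, 7))
  perfect <- confusion_metrics(truth, truth, "A")
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(100, 100, 100))
  flipped <- confusion_metrics(ifelse(truth == "A", "B", "A"), truth, "A")
  expect_equal(c(flipped$sensitivity, flipped$specificity, flipped$accuracy),
               c(0, 0, 0))
  expect_error(confusion_metrics(truth, rep("A", 12), "A"), "two classes")
  expect_error(confusion_metrics(truth, truth, "C"), "absent")
})

test_that("accuracy equals the prevalence-weighted mean of sensitivity and specificity", {
  set.seed(6)
  for (i in 1:10) {
    n_a <- sample(3:20, 1)
    n_b <- sample(3:20, 1)
    truth <- rep(c("A", "B"), c(n_a, n_b))
    pred <- sample(c("A", "B"), n_a + n_b, replace = TRUE)
    m <- confusion_metrics(pred, truth, "A")
    weighted <- (n_a * m$sensitivity + n_b * m$specificity) / (n_a + n_b)
    expect_equal(m$accuracy, round((m$tp + m$tn) / (n_a + n_b) * 100, 2))
    expect_lt(abs(m$accuracy - weighted), 0.02)   # only 2-decimal rounding apart
  }
})

test_that("feature tables carry the selected edges per subject", {
  sim <- make_cohort(cohort_spec(n_group_a = 4, n_group_b = 4, n_regions = 5,
                                 seed = 11))
  ft <- build_feature_table(sim$stack, tibble::tibble(i = c(1, 2), j = c(3, 4)))
  expect_equal(nrow(ft), 8)
  expect_equal(ncol(ft), 5)   # id, group, score + 2 edges
  expect_equal(ft[[4]], sim$stack$matrices[1, 3, ])
  expect_error(loocv_linear_svm(dplyr::mutate(ft, group = factor("X"))),
               "two levels")
})

test_that("glance on a LOOCV report summarizes metrics and settings", {
  feats <- separated_features(n_a = 5, n_b = 6)
  gl <- glance(loocv_linear_svm(feats, regularization = 2))
  expect_equal(gl$n_folds, 11)
  expect_equal(gl$regularization, 2)
  expect_equal(gl$positive_class, "SWEDD")
  expect_equal(gl$tp + gl$fn, 5)
  expect_equal(gl$tn + gl$fp, 6)
})
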