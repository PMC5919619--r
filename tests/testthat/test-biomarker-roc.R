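# Univariate ROC and multivariate panel models.

# pair-counting AUC oracle
auc_oracle <- function(values, labels, positive = "cpdm") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  max(s, length(pos) * length(neg) - s) / (length(pos) * length(neg))
}

test_that("perfect separation gives AUC 1 and a separating threshold", {
  v <- c(1:5, 11:15)
  lab <- rep(c("WT", "cpdm"), each = 5)
  r <- univariate_roc(v, lab)
  expect_equal(r$auc, 1)
  expect_gt(r$threshold, 5)
  expect_lt(r$threshold, 11)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
})

test_that("labels independent of values give AUC near 0.5", {
  set.seed(55)
  v <- stats::rnorm(10000)
  lab <- sample(rep(c("WT", "cpdm"), each = 5000))
  expect_equal(univariate_roc(v, lab)$auc, 0.5, tolerance = 0.02)
})

test_that("one crossing sample among 28 gives the rank-formula AUC 0.964", {
  # 14 per class; one WT value overtakes 7 cpdm values -> 7 discordant pairs
  wt <- c(1:13, 21.5)
  cpdm <- 15:28
  v <- c(wt, cpdm)
  lab <- rep(c("WT", "cpdm"), each = 14)
  r <- univariate_roc(v, lab)
  expect_equal(r$auc, 1 - 7 / 196, tolerance = 1e-12)
  expect_equal(r$auc, 0.964, tolerance = 5e-4)
  expect_equal(r$auc, auc_oracle(v, lab), tolerance = 1e-12)
})

test_that("rank AUC equals trapezoidal AUC and the pair-count oracle", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    v <- sample(round(stats::rnorm(n), sample(0:1, 1)))  # forces ties
    lab <- sample(rep_len(c("WT", "cpdm"), n))
    if (length(unique(lab)) < 2) next
    a1 <- univariate_roc(v, lab)$auc
    expect_equal(a1, trapezoid_auc(v, lab), tolerance = 1e-12)
    expect_equal(a1, auc_oracle(v, lab), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(88)
  for (i in 1:20) {
    v <- stats::rnorm(30) + rep(c(0, 1), each = 15)
    lab <- rep(c("WT", "cpdm"), each = 15)
    ref <- as.numeric(pROC::auc(pROC::roc(lab, v, levels = c("WT", "cpdm"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(univariate_roc(v, lab)$auc, max(ref, 1 - ref),
                 tolerance = 1e-12)
  }
})

test_that("single-class labels are an error", {
  expect_error(univariate_roc(1:5, rep("WT", 5)), "both classes")
})

test_that("an uninformative panel cross-validates near chance", {
  cfg <- small_config()
  cfg$effects[] <- 1
  fm <- ingest_cohort(generate_cohort(cfg, seed = 41),
                      small_methods()$positive)
  model <- fit_panel(fm, c("666.35/264.1+", "554.2/264.1+", "538.3/264.1+"),
                     cv_repeats = 50, seed = 2)
  expect_lt(model$cv_auc, 0.85)
  expect_gt(model$cv_auc, 0.15)
})

test_that("panel fitting is seeded and refuses unknown features", {
  cfg <- small_config()
  fm <- ingest_cohort(generate_cohort(cfg, seed = 4),
                      small_methods()$positive)
  m1 <- fit_panel(fm, biomarker_panel("ceramide"), cv_repeats = 20, seed = 9)
  m2 <- fit_panel(fm, biomarker_panel("ceramide"), cv_repeats = 20, seed = 9)
  expect_equal(m1$cv_auc, m2$cv_auc)
  expect_equal(m1$cv_accuracy, m2$cv_accuracy)
  expect_error(fit_panel(fm, c("nope/1+")), "absent")
})

test_that("validation prediction is blind, complete and accurate", {
  cfg <- cohort_config()
  fm <- ingest_cohort(generate_cohort(cfg, seed = 10),
                      reference_screening_methods()$positive)
  model <- fit_panel(fm, biomarker_panel("ceramide"), cv_repeats = 20,
                     seed = 3)
  pred <- predict_validation(model, fm)
  expect_equal(nrow(pred), 21)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_equal(attr(pred, "accuracy"), 1)
  # leakage guard: scoring the training split must fail
  expect_error(predict_validation(model, fm, split = "testing"),
               "seen in training")
})

test_that("an empty validation split yields an empty result, not an error", {
  cfg <- small_config()
  tab <- generate_cohort(cfg, seed = 12)
  tab <- tab[tab$split == "testing", ]
  fm <- ingest_cohort(tab, small_methods()$positive)
  model <- fit_panel(fm, biomarker_panel("ceramide"), cv_repeats = 10,
                     seed = 1)
  pred <- predict_validation(model, fm)
  expect_equal(nrow(pred), 0)
  expect_true(is.na(attr(pred, "accuracy")))
})

test_that("shuffling validation labels never changes the fitted weights", {
  cfg <- small_config()
  tab <- generate_cohort(cfg, seed = 19)
  fm <- ingest_cohort(tab, small_methods()$positive)
  m1 <- fit_panel(fm, biomarker_panel("ceramide"), cv_repeats = 10, seed = 5)
  fm2 <- fm
  vidx <- fm2$samples$split == "validation"
  set.seed(1)
  fm2$samples$group[vidx] <- sample(fm2$samples$group[vidx])
  m2 <- fit_panel(fm2, biomarker_panel("ceramide"), cv_repeats = 10,
                  seed = 5)
  expect_equal(m1$fit$loadings$X, m2$fit$loadings$X)
})

test_that("raising a panel member's fold change never hurts expected AUC", {
  aucs <- vapply(c(1, 5, 20), function(fc) {
    cfg <- small_config()
    cfg$effects["666.35/264.1+"] <- fc
    cfg$effects["538.3/264.1+"] <- 1
    mean(vapply(1:3, function(s) {
      fm <- ingest_cohort(generate_cohort(cfg, seed = 100 + s),
                          small_methods()$positive)
      fit_panel(fm, "666.35/264.1+", cv_repeats = 20, seed = s)$cv_auc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.05))
  expect_gt(aucs[3], 0.95)
})

test_that("the random-forest panel matches the PLS-DA call on easy data", {
  skip_if_not_installed("randomForest")
  cfg <- cohort_config()
  fm <- ingest_cohort(generate_cohort(cfg, seed = 30),
                      reference_screening_methods()$positive)
  model <- fit_panel(fm, biomarker_panel("ceramide"), algorithm = "rf",
                     cv_repeats = 10, n_tree = 200, seed = 8)
  pred <- predict_validation(model, fm)
  expect_equal(attr(pred, "accuracy"), 1)
})
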