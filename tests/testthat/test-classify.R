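test_that("metric formulas match hand arithmetic on integer counts", {
  m <- compute_metrics(list(TP = 9, FP = 1, TN = 8, FN = 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11)
  expect_equal(m$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  perfect <- compute_metrics(list(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # zero denominators surface as explicit undefined markers
  degenerate <- compute_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_true(is.na(degenerate$precision))
  expect_true(is.na(degenerate$f1))
  expect_equal(degenerate$accuracy, 0.5)
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "record")
})

test_that("confusion counts partition the evaluated records", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  pred <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 5)
  expect_equal(cc$TP, 2); expect_equal(cc$FN, 1)
  expect_equal(cc$FP, 1); expect_equal(cc$TN, 1)
})

test_that("fold assignment partitions records and stratifies the label", {
  y <- rep(c(TRUE, FALSE), c(30, 70))
  folds <- gwobesity:::make_folds(y, 10, seed = 1)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), 100)
  expect_true(all(table(folds) == 10))
  expect_true(all(table(folds[y]) == 3))  # 3 obese in every fold
})

test_that("cross-validation separates a separable problem and is deterministic", {
  df <- make_separable(400, seed = 2)
  cv <- kfold_cv(df, model_spec("logistic"), k = 5, seed = 3,
                 features = c("x1", "x2"))
  expect_gte(cv$pooled$accuracy, 0.99)
  cv2 <- kfold_cv(df, model_spec("logistic"), k = 5, seed = 3,
                  features = c("x1", "x2"))
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$pooled, cv2$pooled)
  # every record lands in exactly one test fold
  expect_equal(length(cv$folds), nrow(df))
  # per-fold table covers all folds
  expect_equal(sort(cv$per_fold$fold), 1:5)
})

test_that("all four model families fit, predict and cross-validate", {
  tr <- synthetic_truth(seed = 30)
  rec <- generate_individual_records(600, tr)
  feats <- individual_feature_names(rec)
  for (fam in c("logistic", "random_forest", "xgboost", "gradient_boosting")) {
    sp <- model_spec(fam, trees = 100, nrounds = 30)
    mod <- fit_classifier(sp, rec, features = feats, seed = 4)
    pr <- predict(mod, rec)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_gt(mean((pr >= 0.5) == rec$obese), 0.7)
  }
})

test_that("model comparison ranks by pooled accuracy with stable ties", {
  tr <- synthetic_truth(seed = 31)
  rec <- generate_individual_records(500, tr)
  specs <- list(model_spec("logistic", label = "logit_a"),
                model_spec("logistic", label = "logit_b"),
                model_spec("gradient_boosting", nrounds = 30))
  cmp <- compare_models(rec, specs, k = 4, seed = 5)
  r <- cmp$ranking
  # sorted non-increasing by accuracy
  expect_true(all(diff(r$accuracy) <= 1e-12))
  # identical specs on identical folds -> identical metrics, order preserved
  expect_equal(r$accuracy[r$model == "logit_a"], r$accuracy[r$model == "logit_b"])
  expect_lt(which(r$model == "logit_a"), which(r$model == "logit_b"))
  # single spec -> ranking of length 1
  one <- compare_models(rec, specs[1], k = 4, seed = 5)
  expect_equal(nrow(one$ranking), 1)
})

test_that("a training fold missing one class is reported, not silently fit", {
  df <- data.frame(x1 = rnorm(20), obese = rep(c(TRUE, FALSE), c(2, 18)))
  folds <- c(1, 1, rep(1:2, 9))  # both obese records sit in fold 1's test split
  cv <- kfold_cv(df, model_spec("logistic"), k = 2, seed = 1,
                 features = "x1", folds = folds)
  expect_true(length(cv$failed_folds) >= 1)
})
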