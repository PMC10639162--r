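# small boosted ensemble on a handful of features, reused across tests
fit_small_ensemble <- function(n = 300, p = 4, nrounds = 5, depth = 3,
                               seed = 1) {
  gwobesity:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("f", seq_len(p))
    y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.5) > 0)
    df <- as.data.frame(X)
    df$obese <- y == 1
    sp <- model_spec("gradient_boosting", nrounds = nrounds, max_depth = depth)
    list(model = fit_classifier(sp, df, features = colnames(X), seed = seed),
         df = df)
  })
}

test_that("attributions match brute-force Shapley enumeration on small trees", {
  fe <- fit_small_ensemble(n = 250, p = 4, nrounds = 4, depth = 3, seed = 11)
  sh <- compute_shap(fe$model, fe$df)
  tr <- gwobesity:::parse_booster(fe$model$fit, sh$features)
  for (i in c(1, 7, 42, 101, 250)) {
    x <- as.numeric(fe$df[i, sh$features])
    expect_equal(unname(sh$values[i, ]), oracle_shap(tr, x, 4),
                 tolerance = 1e-9)
  }
})

test_that("local accuracy: base plus attributions equals the margin on every record", {
  fe <- fit_small_ensemble(n = 400, p = 4, nrounds = 30, seed = 12)
  sh <- compute_shap(fe$model, fe$df)
  expect_lt(max(abs(sh$base_value + rowSums(sh$values) - sh$margin)), 1e-6)
})

test_that("attributions agree with the booster's own (float32) TreeSHAP", {
  fe <- fit_small_ensemble(n = 400, p = 4, nrounds = 30, seed = 13)
  sh <- compute_shap(fe$model, fe$df)
  X <- as.matrix(fe$df[, sh$features]); storage.mode(X) <- "double"
  ctr <- predict(fe$model$fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  expect_lt(max(abs(ctr[, sh$features] - sh$values)), 1e-4)
  mg <- predict(fe$model$fit, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
  expect_lt(max(abs(mg - sh$margin)), 1e-4)
})

test_that("a single stump attributes only through its split feature", {
  fe <- fit_small_ensemble(n = 300, p = 4, nrounds = 1, depth = 1, seed = 14)
  sh <- compute_shap(fe$model, fe$df)
  tr <- gwobesity:::parse_booster(fe$model$fit, sh$features)
  split_feat <- sh$features[tr$feature[tr$feature >= 0][1] + 1]
  others <- setdiff(sh$features, split_feat)
  expect_true(all(sh$values[, others] == 0))
  expect_true(any(sh$values[, split_feat] != 0))
})

test_that("a constant feature receives zero attribution", {
  fe <- fit_small_ensemble(n = 300, p = 3, nrounds = 10, seed = 15)
  df <- fe$df
  df$flat <- 3.0
  sp <- model_spec("gradient_boosting", nrounds = 10)
  mod <- fit_classifier(sp, df, features = c("f1", "f2", "f3", "flat"), seed = 2)
  sh <- compute_shap(mod, df)
  expect_true(all(abs(sh$values[, "flat"]) < 1e-12))
})

test_that("ranking sorts by mean absolute attribution with alphabetical ties", {
  sh <- structure(list(values = cbind(b = c(2, -2), a = c(1, -1), c = c(0, 0)),
                       base_value = 0, margin = c(3, -3),
                       features = c("b", "a", "c"),
                       X = data.frame(b = 1:2, a = 1:2, c = 1:2)),
                  class = "shap_matrix")
  rk <- rank_features(sh)
  expect_equal(rk$feature, c("b", "a", "c"))
  expect_equal(rk$mean_abs_shap, c(2, 1, 0))
  # all-zero attributions -> alphabetical order
  sh$values[] <- 0
  expect_equal(rank_features(sh)$feature, c("a", "b", "c"))
})

test_that("ranking is invariant to record order and top-k is a prefix", {
  fe <- fit_small_ensemble(n = 300, p = 4, nrounds = 20, seed = 16)
  sh <- compute_shap(fe$model, fe$df)
  rk <- rank_features(sh)
  shuf <- compute_shap(fe$model, fe$df[sample(nrow(fe$df)), ])
  expect_equal(rank_features(shuf), rk)
  expect_identical(top_k(rk, 2), rk$feature[1:2])
  expect_identical(top_k(rk, 99), rk$feature)  # k > p -> all p names
  expect_identical(top_k(rk, 1), rk$feature[1])
})

test_that("dependence export pairs raw values with attributions", {
  fe <- fit_small_ensemble(n = 200, p = 4, nrounds = 20, seed = 17)
  sh <- compute_shap(fe$model, fe$df)
  dep <- dependence_export(sh, "f1")
  expect_equal(nrow(dep), 200)
  expect_equal(dep$value, fe$df$f1)
  # monotone generative effect -> positive rank correlation
  expect_gt(cor(dep$value, dep$shap, method = "spearman"), 0)
  expect_error(dependence_export(sh, "nope"), "unknown feature")
})

test_that("shap rejects non-tree models and mismatched features", {
  tr <- synthetic_truth(seed = 18)
  rec <- generate_individual_records(200, tr)
  logit <- fit_classifier(model_spec("logistic"), rec)
  expect_error(compute_shap(logit, rec), "boosted tree")
  gb <- fit_classifier(model_spec("gradient_boosting", nrounds = 5), rec)
  expect_error(compute_shap(gb, rec[, 1:3]), "missing model features")
})
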