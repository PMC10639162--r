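#' Confusion counts
#'
#' @param truth logical (or 0/1) true labels, `TRUE` = obese.
#' @param predicted logical (or 0/1) predicted labels.
#' @return Object of class `confusion_counts` with integer `TP`, `FP`, `TN`,
#'   `FN` (positive class = obese).
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  stopifnot(length(truth) == length(predicted),
            !any(is.na(truth)), !any(is.na(predicted)))
  structure(list(TP = sum(truth & predicted),
                 FP = sum(!truth & predicted),
                 TN = sum(!truth & !predicted),
                 FN = sum(truth & !predicted)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, and F1 as the harmonic mean of precision and recall,
#' `2PR/(P+R)`. A metric whose denominator is zero is reported as `NA`
#' (an explicit undefined marker), never silently as 0.
#'
#' @param counts a [confusion_counts()] object, or a list with fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @return Object of class `metric_set`: `accuracy`, `precision`, `recall`,
#'   `f1`, plus the counts.
#' @examples
#' compute_metrics(confusion_counts(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)))
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total <= 0) stop_invalid("compute_metrics needs at least one record")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (TP + TN) / total,
                 precision = precision, recall = recall, f1 = f1,
                 counts = list(TP = TP, FP = FP, TN = TN, FN = FN)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %s | recall %s | f1 %s\n",
              x$accuracy,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall)),
              ifelse(is.na(x$f1), "NA", sprintf("%.4f", x$f1))))
  invisible(x)
}

#' Candidate classifier specification
#'
#' Pluggable wrappers over established learners; the bespoke content of this
#' module is the cross-validation/oversampling protocol and the metrics, not
#' the learners themselves. Families:
#' \describe{
#'   \item{`logistic`}{logistic regression via [stats::glm()].}
#'   \item{`random_forest`}{random forest via `ranger` (default 5,000 trees,
#'     the study-scale setting; override `trees` for desk-scale work).}
#'   \item{`xgboost`}{gradient-boosted trees via `xgboost` (default depth 6,
#'     shrinkage 0.3, 100 rounds).}
#'   \item{`gradient_boosting`}{classical gradient boosting realized as an
#'     `xgboost` booster with depth-3 trees, shrinkage 0.1 and no column
#'     subsampling.}
#' }
#' The two boosted families expose exact tree-path Shapley attribution via
#' [compute_shap()].
#'
#' @param family one of `"logistic"`, `"random_forest"`, `"xgboost"`,
#'   `"gradient_boosting"`.
#' @param trees number of trees for the random forest.
#' @param nrounds boosting rounds for the boosted families.
#' @param max_depth,eta tree depth and learning rate for the boosted families
#'   (defaults: 6/0.3 for `xgboost`, 3/0.1 for `gradient_boosting`).
#' @param label name used in reports; defaults to the family name.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("logistic", "random_forest", "xgboost",
                                  "gradient_boosting"),
                       trees = 5000, nrounds = 100,
                       max_depth = NULL, eta = NULL, label = NULL) {
  family <- match.arg(family)
  if (is.null(max_depth)) max_depth <- if (family == "gradient_boosting") 3L else 6L
  if (is.null(eta)) eta <- if (family == "gradient_boosting") 0.1 else 0.3
  structure(list(family = family, trees = as.integer(trees),
                 nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 label = if (is.null(label)) family else label),
            class = "model_spec")
}

#' Fit a classifier to labeled records
#'
#' @param spec a [model_spec()].
#' @param records data frame holding features and the label column.
#' @param features feature column names; default
#'   [individual_feature_names()].
#' @param label_col label column name (logical/0-1), default `"obese"`.
#' @param seed integer seed for the stochastic learners.
#' @return Object of class `obesity_model` with a [predict][stats::predict]
#'   method returning the obese-class probability.
#' @export
fit_classifier <- function(spec, records,
                           features = individual_feature_names(records),
                           label_col = "obese", seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(records),
            all(features %in% names(records)), label_col %in% names(records))
  y <- as.logical(records[[label_col]])
  if (length(unique(y)) < 2)
    stop_invalid("training data must contain both classes")
  X <- as.matrix(records[, features, drop = FALSE])
  storage.mode(X) <- "double"

  fit <- switch(
    spec$family,
    logistic = {
      df <- data.frame(X, .y = y)
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    random_forest = {
      df <- data.frame(X, .y = factor(y, levels = c(FALSE, TRUE)))
      ranger::ranger(.y ~ ., data = df, num.trees = spec$trees,
                     probability = TRUE, seed = seed, num.threads = 1)
    },
    xgboost = ,
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
      params <- list(objective = "binary:logistic",
                     max_depth = spec$max_depth, eta = spec$eta,
                     subsample = 1, colsample_bytree = 1,
                     base_score = 0.5, nthread = 1,
                     seed = seed)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = spec$nrounds, verbose = 0)
    })
  structure(list(spec = spec, fit = fit, features = features,
                 label_col = label_col, seed = seed),
            class = "obesity_model")
}

#' @export
print.obesity_model <- function(x, ...) {
  cat(sprintf("obesity classifier [%s] on %d features\n",
              x$spec$label, length(x$features)))
  invisible(x)
}

#' @param object an `obesity_model`.
#' @param newdata data frame holding the model's feature columns.
#' @param ... unused.
#' @return Numeric vector of obese-class probabilities.
#' @rdname fit_classifier
#' @export
predict.obesity_model <- function(object, newdata, ...) {
  if (!all(object$features %in% names(newdata)))
    stop_invalid("newdata is missing feature columns: %s",
                 paste(setdiff(object$features, names(newdata)), collapse = ", "))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  switch(
    object$spec$family,
    logistic = as.numeric(predict(object$fit, newdata = as.data.frame(X),
                                  type = "response")),
    random_forest = {
      pr <- predict(object$fit, data = as.data.frame(X),
                    num.threads = 1)$predictions
      as.numeric(pr[, "TRUE"])
    },
    as.numeric(predict(object$fit, xgboost::xgb.DMatrix(X))))
}

# stratified fold assignment: within each class, a shuffled round-robin
make_folds <- function(labels, k, seed) {
  labels <- as.logical(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Stratified k-fold cross-validation with in-fold oversampling
#'
#' Folds are stratified by label. Within each training split the minority
#' class is randomly oversampled to a 1:1 balance ([random_oversample()]);
#' test folds are never touched, so reported metrics reflect the natural
#' class ratio. Fold confusion counts are pooled into one table; per-fold and
#' fold-averaged metrics are also reported, since a published summary could
#' reflect either convention.
#'
#' @inheritParams fit_classifier
#' @param k number of folds (>= 2), default 10.
#' @param seed integer seed controlling fold assignment, oversampling and
#'   learner randomness.
#' @param oversample logical; set `FALSE` to skip training-fold balancing.
#' @param folds optional precomputed fold assignment (integer vector in
#'   `1:k`), e.g. to evaluate several specs on identical folds.
#' @return Object of class `cv_result`: `pooled` ([compute_metrics()] on the
#'   pooled counts), `per_fold` (data frame), `fold_mean` (mean of defined
#'   per-fold metrics), `folds`, `failed_folds`.
#' @export
kfold_cv <- function(records, spec, k = 10, seed = 1L,
                     features = individual_feature_names(records),
                     label_col = "obese", oversample = TRUE, folds = NULL) {
  stopifnot(k >= 2, nrow(records) >= k)
  y <- as.logical(records[[label_col]])
  if (is.null(folds)) folds <- make_folds(y, k, derive_seed(seed, "folds"))
  stopifnot(length(folds) == nrow(records))

  per_fold <- vector("list", k)
  failed <- character(0)
  pooled <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (f in seq_len(k)) {
    train <- records[folds != f, , drop = FALSE]
    test <- records[folds == f, , drop = FALSE]
    if (length(unique(as.logical(train[[label_col]]))) < 2) {
      failed <- c(failed, sprintf("fold %d: a class is absent from training data", f))
      next
    }
    if (oversample)
      train <- random_oversample(train, seed = derive_seed(seed, paste0("os", f)),
                                 label_col = label_col)
    mod <- fit_classifier(spec, train, features = features,
                          label_col = label_col,
                          seed = derive_seed(seed, paste0("fit", f)))
    pred <- predict(mod, test) >= 0.5
    cc <- confusion_counts(test[[label_col]], pred)
    m <- compute_metrics(cc)
    per_fold[[f]] <- data.frame(fold = f, TP = cc$TP, FP = cc$FP, TN = cc$TN,
                                FN = cc$FN, accuracy = m$accuracy,
                                precision = m$precision, recall = m$recall,
                                f1 = m$f1)
    pooled <- Map(`+`, pooled, cc[c("TP", "FP", "TN", "FN")])
  }
  per_fold <- do.call(rbind, per_fold)
  fold_mean <- if (!is.null(per_fold))
    colMeans(per_fold[, c("accuracy", "precision", "recall", "f1")],
             na.rm = TRUE) else NULL
  structure(list(pooled = compute_metrics(pooled),
                 per_fold = per_fold,
                 fold_mean = fold_mean,
                 folds = folds, k = k, spec = spec,
                 failed_folds = failed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV [%s], pooled: ", x$k, x$spec$label))
  print(x$pooled)
  if (length(x$failed_folds))
    cat("  failed folds:", paste(x$failed_folds, collapse = "; "), "\n")
  invisible(x)
}

#' Compare candidate classifiers on identical folds
#'
#' Evaluates each specification with [kfold_cv()] on one shared stratified
#' fold assignment and ranks the specs by pooled accuracy, breaking ties by
#' pooled F1 and then by spec order.
#'
#' @inheritParams kfold_cv
#' @param specs list of [model_spec()] objects (>= 2 for a comparison).
#' @return Object of class `model_comparison`: `ranking` (data frame, best
#'   first), `cv` (named list of `cv_result`s), `folds`.
#' @export
compare_models <- function(records, specs, k = 10, seed = 1L,
                           features = individual_feature_names(records),
                           label_col = "obese", oversample = TRUE) {
  stopifnot(is.list(specs), length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "model_spec")))
  folds <- make_folds(as.logical(records[[label_col]]), k,
                      derive_seed(seed, "folds"))
  cvs <- lapply(specs, function(sp)
    kfold_cv(records, sp, k = k, seed = seed, features = features,
             label_col = label_col, oversample = oversample, folds = folds))
  labels <- vapply(specs, `[[`, character(1), "label")
  names(cvs) <- make.unique(labels)
  tab <- data.frame(
    model = names(cvs),
    accuracy = vapply(cvs, function(cv) cv$pooled$accuracy, numeric(1)),
    precision = vapply(cvs, function(cv) cv$pooled$precision, numeric(1)),
    recall = vapply(cvs, function(cv) cv$pooled$recall, numeric(1)),
    f1 = vapply(cvs, function(cv) cv$pooled$f1, numeric(1)),
    row.names = NULL)
  ord <- order(-tab$accuracy, -ifelse(is.na(tab$f1), -Inf, tab$f1),
               seq_len(nrow(tab)))
  structure(list(ranking = tab[ord, , drop = FALSE], cv = cvs, folds = folds),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (pooled CV metrics, best first):\n")
  print(x$ranking, row.names = FALSE, digits = 4)
  invisible(x)
}
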