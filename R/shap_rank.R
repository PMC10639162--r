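# --- tree parsing -----------------------------------------------------------

# Flatten a fitted xgboost booster into concatenated node arrays for the
# double-precision TreeSHAP core. Split decisions follow xgboost semantics:
# take the "Yes" branch when x < threshold (inputs here contain no missing
# values, so the default branch never fires).
parse_booster <- function(booster, features) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  value_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  idx <- setNames(seq_len(nrow(dt)) - 1L, dt$ID)  # global 0-based node index
  is_leaf <- dt$Feature == "Leaf"
  feat_idx <- match(dt$Feature, features) - 1L
  feat_idx[is_leaf] <- -1L
  if (any(is.na(feat_idx) & !is_leaf))
    stop_invalid("booster splits on features not in the supplied feature set")
  roots <- idx[dt$ID[dt$Node == 0]]
  list(roots = as.integer(roots),
       feature = as.integer(feat_idx),
       threshold = ifelse(is_leaf, 0, dt$Split),
       yes = as.integer(ifelse(is_leaf, -1L, idx[dt$Yes])),
       no = as.integer(ifelse(is_leaf, -1L, idx[dt$No])),
       value = ifelse(is_leaf, dt[[value_col]], 0),
       cover = dt$Cover)
}

#' Per-record Shapley attributions for a boosted tree ensemble
#'
#' Computes exact tree-path Shapley values (the path-dependent TreeSHAP
#' algorithm) for every record and feature, on the log-odds margin of the
#' obese class: positive attributions push the prediction toward obesity.
#' The recursion runs in double precision over the parsed trees, so the
#' local-accuracy identity -- base value plus the row sum of attributions
#' equals the margin prediction -- holds to floating-point accuracy. Cover
#' (the training hessian mass per node) supplies the background distribution,
#' matching the standard tree-path-dependent formulation.
#'
#' @param model an [fit_classifier()] model of family `"xgboost"` or
#'   `"gradient_boosting"`, or a raw `xgb.Booster`.
#' @param X data frame (or matrix) containing the model's feature columns,
#'   no missing values.
#' @return Object of class `shap_matrix`: `values` (n x p matrix of signed
#'   attributions), `base_value` (expected margin under the cover
#'   distribution), `margin` (per-record margin recomputed from the parsed
#'   trees), `features`, and `X` (the feature columns used).
#' @export
compute_shap <- function(model, X) {
  if (inherits(model, "obesity_model")) {
    if (!model$spec$family %in% c("xgboost", "gradient_boosting"))
      stop_invalid("compute_shap requires a boosted tree ensemble (family xgboost or gradient_boosting), got %s",
                   model$spec$family)
    booster <- model$fit
    features <- model$features
  } else if (inherits(model, "xgb.Booster")) {
    booster <- model
    features <- xgboost::getinfo(booster, "feature_name")
    if (is.null(features) || !length(features))
      stop_invalid("booster carries no feature names")
  } else {
    stop_invalid("model must be an obesity_model or an xgb.Booster")
  }
  X <- as.data.frame(X)
  if (!all(features %in% names(X)))
    stop_invalid("X is missing model features: %s",
                 paste(setdiff(features, names(X)), collapse = ", "))
  Xm <- as.matrix(X[, features, drop = FALSE])
  storage.mode(Xm) <- "double"
  if (any(!is.finite(Xm))) stop_invalid("X must be finite (no missing values)")

  tr <- parse_booster(booster, features)
  raw <- treeshap_predict(Xm, tr$roots, tr$feature, tr$threshold,
                          tr$yes, tr$no, tr$value, tr$cover)
  p <- length(features)
  values <- raw[, seq_len(p), drop = FALSE]
  colnames(values) <- features
  structure(list(values = values,
                 base_value = raw[1, p + 1],
                 margin = raw[, p + 2],
                 features = features,
                 X = X[, features, drop = FALSE]),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d records x %d features (base value %.4f)\n",
              nrow(x$values), length(x$features), x$base_value))
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' Importance is the mean over records of the absolute Shapley attribution
#' (the ordering used by standard summary plots). Ties are broken
#' alphabetically by feature name so rankings are reproducible.
#'
#' @param shap a [compute_shap()] result.
#' @param district_id optional label carried into the ranking.
#' @return Object of class `shap_ranking`: data frame with `rank`, `feature`,
#'   `mean_abs_shap`, sorted non-increasing.
#' @export
rank_features <- function(shap, district_id = NULL) {
  stopifnot(inherits(shap, "shap_matrix"), nrow(shap$values) >= 1)
  imp <- colMeans(abs(shap$values))
  ord <- order(-imp, names(imp))
  out <- data.frame(rank = seq_along(imp),
                    feature = names(imp)[ord],
                    mean_abs_shap = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(district_id)) out <- cbind(district_id = district_id, out)
  class(out) <- c("shap_ranking", "data.frame")
  out
}

#' Top-k features of a Shapley ranking
#'
#' @param ranking a [rank_features()] result.
#' @param k number of features, default 5.
#' @return Character vector: the first `min(k, p)` feature names.
#' @export
top_k <- function(ranking, k = 5) {
  stopifnot(inherits(ranking, "shap_ranking"), k >= 1)
  ranking$feature[seq_len(min(k, nrow(ranking)))]
}

#' Dependence-curve export for one feature
#'
#' One row per record: the raw feature value and that record's attribution
#' for the feature, ready for scatter rendering (the per-feature dependence
#' view of how responses relate to the obesity margin).
#'
#' @param shap a [compute_shap()] result.
#' @param feature feature name.
#' @param X optional data frame of raw feature values; defaults to the
#'   feature columns stored in `shap`.
#' @return Data frame with columns `value` and `shap`.
#' @export
dependence_export <- function(shap, feature, X = shap$X) {
  stopifnot(inherits(shap, "shap_matrix"))
  if (!feature %in% shap$features)
    stop_invalid("unknown feature: %s", feature)
  stopifnot(nrow(X) == nrow(shap$values), feature %in% names(X))
  data.frame(value = X[[feature]],
             shap = unname(shap$values[, feature]))
}
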