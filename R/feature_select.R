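#' Variance inflation factors
#'
#' VIF of feature *j* is `1 / (1 - R2_j)`, where `R2_j` is the coefficient of
#' determination from regressing feature *j* on all other features (with
#' intercept). Exactly collinear features are reported as `Inf`.
#'
#' @param X numeric data frame or matrix of features (>= 2 columns, more rows
#'   than columns, no constant column).
#' @return Named numeric vector of VIFs (>= 1, or `Inf`).
#' @export
compute_vif <- function(X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 2) stop_invalid("compute_vif needs at least 2 features")
  if (nrow(X) <= p) stop_invalid("compute_vif needs more rows than features")
  if (!all(vapply(X, is.numeric, logical(1))))
    stop_invalid("all features must be numeric")
  const <- vapply(X, function(x) var(x) == 0, logical(1))
  if (any(const))
    stop_invalid("constant column(s): %s",
                 paste(names(X)[const], collapse = ", "))
  vif <- vapply(seq_len(p), function(j) {
    fit <- lm(X[[j]] ~ ., data = X[, -j, drop = FALSE])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[[j]] - mean(X[[j]]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(X)
  vif
}

#' Iterative VIF pruning
#'
#' Repeatedly removes the single feature with the largest VIF above the
#' threshold and recomputes, until all surviving features have VIF at or
#' below the threshold. Ties are broken by earliest column position. The
#' default threshold of 30 keeps moderately collinear survey items while
#' removing redundant ones; a stricter conventional threshold of 10 would
#' discard informative factors in this setting.
#'
#' @param X numeric feature table.
#' @param threshold VIF threshold, default 30.
#' @return A list of class `vif_report`: `X` (surviving table), `vif`
#'   (final VIFs), `removal_order` (features removed, in order),
#'   `removed_vif` (their VIF at removal), `threshold`.
#' @export
iterative_vif_prune <- function(X, threshold = 30) {
  X <- as.data.frame(X)
  stopifnot(is.numeric(threshold), threshold >= 1)
  removal_order <- character(0)
  removed_vif <- numeric(0)
  repeat {
    vif <- compute_vif(X)
    worst <- which.max(vif)  # first index on ties
    if (vif[worst] <= threshold) break
    removal_order <- c(removal_order, names(X)[worst])
    removed_vif <- c(removed_vif, vif[[worst]])
    X <- X[, -worst, drop = FALSE]
    if (ncol(X) < 2) { vif <- c(); break }
  }
  structure(list(X = X, vif = vif, removal_order = removal_order,
                 removed_vif = removed_vif, threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF pruning at threshold %g: %d feature(s) removed, %d kept\n",
              x$threshold, length(x$removal_order), ncol(x$X)))
  if (length(x$removal_order))
    cat("  removed:", paste(sprintf("%s (VIF %.3g)", x$removal_order,
                                    x$removed_vif), collapse = ", "), "\n")
  invisible(x)
}

#' Relevance screening by multiple linear regression
#'
#' Fits one ordinary least squares regression of the response on all features
#' jointly (with intercept) and drops features whose two-sided coefficient
#' t-test p-value exceeds `alpha`. With a binary obesity label the screen is
#' a linear probability model, which is how the screening step treats the 0/1
#' outcome.
#'
#' @param X numeric feature table (full column rank; run
#'   [iterative_vif_prune()] first).
#' @param y numeric response (a logical label is coerced to 0/1).
#' @param alpha significance threshold, default 0.05.
#' @return A list of class `ols_screen`: `X` (surviving features), `kept`,
#'   `dropped`, `p_values` (all features), `alpha`.
#' @export
ols_screen <- function(X, y, alpha = 0.05) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), alpha > 0, alpha <= 1)
  if (nrow(X) <= ncol(X) + 1)
    stop_invalid("ols_screen needs more rows than features + 1")
  fit <- lm(y ~ ., data = cbind(X, y = y)[, c(names(X), "y")])
  ct <- summary(fit)$coefficients
  if (any(is.na(coef(fit))))
    stop_invalid("rank-deficient design; prune collinear features first")
  pv <- ct[-1, 4]  # drop intercept row
  names(pv) <- names(X)
  kept <- names(pv)[pv <= alpha]
  structure(list(X = X[, kept, drop = FALSE],
                 kept = kept,
                 dropped = setdiff(names(X), kept),
                 p_values = pv,
                 alpha = alpha),
            class = "ols_screen")
}

#' @export
print.ols_screen <- function(x, ...) {
  cat(sprintf("OLS screen at alpha = %g: kept %d of %d features\n",
              x$alpha, length(x$kept), length(x$p_values)))
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Combined feature screening
#'
#' The screening order of the analysis pipeline: multicollinearity pruning by
#' iterative VIF first, then the joint OLS relevance screen on the survivors.
#'
#' @inheritParams iterative_vif_prune
#' @inheritParams ols_screen
#' @return List with `X` (final features), `vif_report`, `ols_report`.
#' @export
screen_features <- function(X, y, threshold = 30, alpha = 0.05) {
  vr <- iterative_vif_prune(X, threshold = threshold)
  sr <- ols_screen(vr$X, y, alpha = alpha)
  list(X = sr$X, vif_report = vr, ols_report = sr)
}
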