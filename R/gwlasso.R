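#' Euclidean inter-district distances
#'
#' @param panel data frame with planar centroid columns `u`, `v` (and
#'   optionally `district_id` used for dimnames).
#' @return Symmetric n x n matrix of Euclidean distances, zero diagonal.
#' @examples
#' pairwise_distances(data.frame(u = c(0, 3), v = c(0, 4)))  # off-diagonal 5
#' @export
pairwise_distances <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("u", "v") %in% names(panel)),
            all(is.finite(panel$u)), all(is.finite(panel$v)))
  d <- as.matrix(dist(panel[, c("u", "v")], method = "euclidean"))
  ids <- if ("district_id" %in% names(panel)) panel$district_id
         else as.character(seq_len(nrow(panel)))
  dimnames(d) <- list(ids, ids)
  d
}

#' Geographic kernel specification
#'
#' The spatial weighting scheme that localizes each district's regression:
#' `gaussian` `w = exp(-d^2 / (2 h^2))`, `bisquare`
#' `w = (1 - (d/h)^2)^2` for `d < h` (0 beyond), `uniform` `w = 1`
#' everywhere (which collapses the model to a single global lasso). A `NULL`
#' bandwidth means "the median pairwise distance", resolved when weights are
#' computed; a smooth kernel at that scale suits a panel of ~25 districts.
#'
#' @param family `"gaussian"`, `"bisquare"` or `"uniform"`.
#' @param bandwidth positive distance scale `h`, or `NULL` for the median
#'   pairwise distance.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "bisquare", "uniform"),
                        bandwidth = NULL) {
  family <- match.arg(family)
  if (!is.null(bandwidth))
    stopifnot(is.numeric(bandwidth), length(bandwidth) == 1L, bandwidth > 0)
  structure(list(family = family, bandwidth = bandwidth),
            class = "kernel_spec")
}

#' Kernel weight matrix from distances
#'
#' @param d distance matrix from [pairwise_distances()].
#' @param spec a [kernel_spec()].
#' @return n x n weight matrix in `[0, 1]` (unit diagonal for gaussian and
#'   uniform kernels), with the resolved bandwidth in attribute `bandwidth`.
#' @export
kernel_weights <- function(d, spec) {
  stopifnot(is.matrix(d), all(d >= 0), inherits(spec, "kernel_spec"))
  h <- spec$bandwidth
  if (is.null(h)) {
    off <- d[upper.tri(d)]
    h <- median(off)
    if (!is.finite(h) || h <= 0) stop_invalid("cannot resolve a positive median bandwidth")
  }
  w <- switch(spec$family,
              gaussian = exp(-d^2 / (2 * h^2)),
              bisquare = ifelse(d < h, (1 - (d / h)^2)^2, 0),
              uniform = array(1, dim(d), dimnames = dimnames(d)))
  attr(w, "bandwidth") <- h
  w
}

#' Weighted lasso by cyclic coordinate descent
#'
#' Solves one focal-location subproblem of the geographically weighted lasso:
#' \deqn{\min_{\beta_0,\beta} \sum_i w_i (y_i - \beta_0 - x_i'\beta)^2 +
#'       \lambda \sum_k |\beta_k|}
#' with an unpenalized intercept, via cyclic coordinate descent with
#' soft-thresholding on weighted-centered covariates. Convergence is declared
#' when the largest coefficient change in a sweep falls below `tol`.
#'
#' @param X n x p numeric covariate matrix.
#' @param y numeric response vector.
#' @param w nonnegative observation weights (at least one positive).
#' @param lambda nonnegative L1 penalty.
#' @param beta_init optional warm-start coefficients.
#' @param tol coefficient-change convergence tolerance, default 1e-8.
#' @param max_sweeps sweep cap, default 10000.
#' @return List of class `weighted_lasso`: `intercept`, `beta` (named),
#'   `lambda`, `converged`, `sweeps`, `objective` (per-sweep trace of the
#'   intercept-profiled penalized objective).
#' @export
fit_weighted_lasso <- function(X, y, w, lambda, beta_init = NULL,
                               tol = 1e-8, max_sweeps = 10000L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y); w <- as.numeric(w)
  stopifnot(nrow(X) == length(y), length(w) == length(y),
            all(is.finite(X)), all(is.finite(y)), all(is.finite(w)),
            is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  if (any(w < 0)) stop_invalid("weights must be nonnegative")
  if (!any(w > 0)) stop_invalid("at least one weight must be positive")
  if (is.null(beta_init)) beta_init <- numeric(ncol(X))
  res <- cd_weighted_lasso(X, y, w, lambda, as.numeric(beta_init),
                           tol, as.integer(max_sweeps))
  names(res$beta) <- colnames(X)
  res$lambda <- lambda
  class(res) <- "weighted_lasso"
  res
}

#' Smallest penalty with an all-zero solution
#'
#' At `beta = 0` the subgradient condition of the weighted lasso objective is
#' `|2 sum_i w_i x~_ik y~_i| <= lambda` per coefficient (tildes denote
#' weighted centering), so the all-zero threshold is twice the largest
#' weighted covariance.
#'
#' @inheritParams fit_weighted_lasso
#' @return The penalty value at and above which all coefficients are zero.
#' @export
lasso_lambda_max <- function(X, y, w) {
  X <- as.matrix(X)
  sw <- sum(w)
  xm <- colSums(X * w) / sw
  ym <- sum(w * y) / sw
  Xc <- sweep(X, 2, xm)
  2 * max(abs(colSums(Xc * (w * (y - ym)))))
}

#' KKT residuals of a weighted lasso solution
#'
#' First-order optimality of
#' `sum w (y - b0 - Xb)^2 + lambda sum |b|`: with residual
#' `r = y - b0 - Xb`, each zero coefficient must satisfy
#' `|2 sum w x_k r| <= lambda` and each nonzero coefficient
#' `2 sum w x_k r = lambda * sign(b_k)`; the unpenalized intercept requires
#' `sum w r = 0`. The largest violation is the solver's correctness
#' certificate.
#'
#' @inheritParams fit_weighted_lasso
#' @param intercept,beta the candidate solution.
#' @return List: `max_violation`, per-coefficient `gradient`
#'   (`2 sum w x_k r`), `violation`, and `intercept_violation`.
#' @export
lasso_kkt_residual <- function(X, y, w, lambda, intercept, beta) {
  X <- as.matrix(X)
  r <- y - intercept - drop(X %*% beta)
  g <- 2 * colSums(X * (w * r))
  viol <- ifelse(beta == 0, pmax(0, abs(g) - lambda),
                 abs(g - lambda * sign(beta)))
  iv <- abs(2 * sum(w * r))
  list(max_violation = max(viol, iv), gradient = g, violation = viol,
       intercept_violation = iv)
}

#' Default penalty grid
#'
#' 30 log-spaced penalties spanning the configured search range 0.001-0.03.
#'
#' @param from,to range endpoints.
#' @param length number of grid points.
#' @export
default_lambda_grid <- function(from = 0.001, to = 0.03, length = 30L) {
  stopifnot(from > 0, to >= from, length >= 1)
  exp(seq(log(from), log(to), length.out = length))
}

#' Penalty selection by leave-one-out weighted prediction error
#'
#' For each candidate penalty, each district carrying positive kernel weight
#' is held out in turn, the subproblem is refit on the remaining districts,
#' and the held-out response is predicted; errors are pooled with the
#' held-out kernel weights, `sum_j w_j (y_j - yhat_j)^2`. The smallest
#' pooled error wins; exact ties go to the larger (more parsimonious)
#' penalty.
#'
#' @inheritParams fit_weighted_lasso
#' @param grid nonempty vector of candidate penalties.
#' @return List: `lambda` (the winner), `grid`, `loo_error` (per candidate).
#' @export
select_lambda <- function(X, y, w, grid = default_lambda_grid()) {
  stopifnot(length(grid) >= 1, all(grid >= 0))
  X <- as.matrix(X)
  held <- which(w > 0)
  if (length(held) < 3) stop_invalid("need at least 3 positively weighted districts")
  errs <- vapply(grid, function(lam) {
    e <- 0
    for (j in held) {
      fit <- fit_weighted_lasso(X[-j, , drop = FALSE], y[-j], w[-j], lam)
      pred <- fit$intercept + drop(X[j, , drop = FALSE] %*% fit$beta)
      e <- e + w[j] * (y[j] - pred)^2
    }
    e
  }, numeric(1))
  best <- max(grid[errs <= min(errs) + 0])  # exact ties -> larger penalty
  list(lambda = best, grid = grid, loo_error = errs)
}

#' Geographically weighted lasso over a district panel
#'
#' Fits one weighted lasso per district: the focal district's kernel weights
#' localize the loss, covariates are standardized to weighted mean 0 /
#' variance 1 before penalization (so penalties and coefficient magnitudes
#' are comparable across factors), the penalty is chosen per district by
#' leave-one-out weighted prediction error within the configured range, and
#' coefficients are reported on both the standardized and the raw scale.
#'
#' @param panel district panel: columns `district_id`, `u`, `v`, `y` plus one
#'   numeric column per factor (see [generate_district_panel()]).
#' @param spec a [kernel_spec()]; default gaussian with median-distance
#'   bandwidth.
#' @param grid penalty grid, default [default_lambda_grid()].
#' @param factors factor column names; default: every numeric column other
#'   than `u`, `v`, `population`, `y`.
#' @return Object of class `gwlasso_fit`: `beta` (districts x factors,
#'   standardized scale), `beta_raw`, `intercept_raw`, `lambda`, `residuals`,
#'   `fitted`, `weights` (kernel matrix, resolved bandwidth in attribute),
#'   `center`/`scale` (per-district weighted moments), `grid`, `spec`,
#'   `district_id`, `factors`, `converged`.
#' @export
fit_gwlasso <- function(panel, spec = kernel_spec("gaussian"),
                        grid = default_lambda_grid(), factors = NULL) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 3,
            all(c("district_id", "u", "v", "y") %in% names(panel)))
  if (is.null(factors))
    factors <- setdiff(names(panel)[vapply(panel, is.numeric, logical(1))],
                       c("u", "v", "population", "y"))
  stopifnot(length(factors) >= 1, all(factors %in% names(panel)))
  n <- nrow(panel); p <- length(factors)
  X <- as.matrix(panel[, factors, drop = FALSE])
  y <- panel$y
  W <- kernel_weights(pairwise_distances(panel), spec)

  beta <- beta_raw <- matrix(NA_real_, n, p,
                             dimnames = list(panel$district_id, factors))
  lambda <- intercept_raw <- fitted <- numeric(n)
  center <- scale_ <- matrix(NA_real_, n, p)
  converged <- logical(n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    sw <- sum(w)
    mu <- colSums(X * w) / sw
    sdev <- sqrt(colSums(sweep(X, 2, mu)^2 * w) / sw)
    if (any(sdev <= 0))
      stop_invalid("factor(s) constant under the weights of district %s",
                   panel$district_id[i])
    Xs <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
    lam <- select_lambda(Xs, y, w, grid)$lambda
    fit <- fit_weighted_lasso(Xs, y, w, lam)
    beta[i, ] <- fit$beta
    beta_raw[i, ] <- fit$beta / sdev
    intercept_raw[i] <- fit$intercept - sum(fit$beta * mu / sdev)
    lambda[i] <- lam
    fitted[i] <- intercept_raw[i] + sum(X[i, ] * beta_raw[i, ])
    center[i, ] <- mu; scale_[i, ] <- sdev
    converged[i] <- fit$converged
  }
  structure(list(beta = beta, beta_raw = beta_raw,
                 intercept_raw = intercept_raw, lambda = lambda,
                 fitted = fitted, residuals = y - fitted,
                 weights = W, center = center, scale = scale_,
                 grid = grid, spec = spec,
                 bandwidth = attr(W, "bandwidth"),
                 district_id = panel$district_id, factors = factors,
                 converged = converged),
            class = "gwlasso_fit")
}

#' @export
print.gwlasso_fit <- function(x, ...) {
  cat(sprintf("Geographically weighted lasso: %d districts, %d factors\n",
              length(x$district_id), length(x$factors)))
  cat(sprintf("  kernel %s, bandwidth %.4g; lambda in [%.4g, %.4g] (selected %.4g-%.4g)\n",
              x$spec$family, x$bandwidth, min(x$grid), max(x$grid),
              min(x$lambda), max(x$lambda)))
  print(summarize_coefficients(x))
  invisible(x)
}

#' Across-district coefficient summary
#'
#' The standard presentation of a spatially varying coefficient fit: per
#' factor, the minimum, mean and maximum coefficient over districts, and the
#' counts of districts with strictly positive (`POS`) and strictly negative
#' (`NEG`) coefficients. Lasso shrinkage produces exact zeros, which are
#' counted in neither column, so `POS + NEG + zeros = n` districts.
#'
#' @param fit a [fit_gwlasso()] result.
#' @param scale `"standardized"` (comparable magnitudes across factors; the
#'   reporting scale) or `"raw"`.
#' @return Data frame of class `gwlasso_summary`: `feature`, `min`, `mean`,
#'   `max`, `pos`, `neg`.
#' @export
summarize_coefficients <- function(fit, scale = c("standardized", "raw")) {
  stopifnot(inherits(fit, "gwlasso_fit"))
  scale <- match.arg(scale)
  B <- if (scale == "standardized") fit$beta else fit$beta_raw
  out <- data.frame(feature = colnames(B),
                    min = apply(B, 2, min),
                    mean = colMeans(B),
                    max = apply(B, 2, max),
                    pos = colSums(B > 0),
                    neg = colSums(B < 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gwlasso_summary", "data.frame")
  out
}

#' @importFrom stats dist
NULL
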