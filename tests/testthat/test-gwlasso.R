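test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  pan <- data.frame(district_id = c("A", "B", "C"),
                    u = c(0, 3, 0), v = c(0, 4, 0))
  d <- pairwise_distances(pan)
  expect_equal(d["A", "B"], 5)
  expect_equal(d["A", "C"], 0)   # identical coordinates
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
})

test_that("kernel families implement their closed forms", {
  d <- matrix(c(0, 1, 1, 0), 2)
  g <- kernel_weights(d, kernel_spec("gaussian", bandwidth = 1))
  expect_equal(diag(g), c(1, 1))
  expect_equal(g[1, 2], exp(-0.5))
  b <- kernel_weights(d, kernel_spec("bisquare", bandwidth = 1))
  expect_equal(b[1, 2], 0)  # d == h is outside the support
  expect_equal(diag(b), c(1, 1))
  b2 <- kernel_weights(d, kernel_spec("bisquare", bandwidth = 2))
  expect_equal(b2[1, 2], (1 - 0.25)^2)
  u <- kernel_weights(d, kernel_spec("uniform", bandwidth = 1))
  expect_true(all(u == 1))
})

random_instance <- function(seed, n = 30, p = 5) {
  gwobesity:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("x", seq_len(p))
    list(X = X, y = drop(X %*% rnorm(p)) + rnorm(n, 0, 0.5),
         w = runif(n, 0.05, 2), lambda = runif(1, 0, 0.05))
  })
}

test_that("solver satisfies KKT and matches weighted least squares at zero penalty", {
  for (seed in 1:25) {
    it <- random_instance(seed)
    f <- fit_weighted_lasso(it$X, it$y, it$w, it$lambda)
    expect_true(f$converged)
    kkt <- lasso_kkt_residual(it$X, it$y, it$w, it$lambda, f$intercept, f$beta)
    expect_lt(kkt$max_violation, 1e-6)
    # objective non-increasing across sweeps
    expect_true(all(diff(f$objective) <= 1e-10))
    f0 <- fit_weighted_lasso(it$X, it$y, it$w, 0)
    expect_equal(unname(c(f0$intercept, f0$beta)),
                 unname(oracle_wls(it$X, it$y, it$w)), tolerance = 1e-6)
  }
})

test_that("solver matches glmnet on the rescaled problem", {
  skip_if_not_installed("glmnet")
  for (seed in 1:10) {
    it <- random_instance(seed, n = 40, p = 6)
    lam <- it$lambda * 30  # exercise a visibly active penalty
    f <- fit_weighted_lasso(it$X, it$y, it$w, lam)
    g <- glmnet::glmnet(it$X, it$y, weights = it$w,
                        lambda = lam / (2 * sum(it$w)),
                        standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(c(f$intercept, f$beta)),
                 as.numeric(stats::coef(g)), tolerance = 1e-5)
  }
})

test_that("full shrinkage above the penalty ceiling, with weighted-mean intercept", {
  for (seed in 1:10) {
    it <- random_instance(seed)
    lmax <- lasso_lambda_max(it$X, it$y, it$w)
    f <- fit_weighted_lasso(it$X, it$y, it$w, lmax * (1 + 1e-10))
    expect_true(all(f$beta == 0))
    expect_equal(f$intercept, sum(it$w * it$y) / sum(it$w))
    # strictly below the ceiling at least one coefficient activates
    f2 <- fit_weighted_lasso(it$X, it$y, it$w, lmax * 0.99)
    expect_true(any(f2$beta != 0))
  }
})

test_that("univariate solution equals the soft-threshold closed form and a grid search", {
  it <- gwobesity:::with_seed(77, {
    x <- rnorm(50); w <- runif(50, 0.2, 1.5)
    sw <- sum(w)
    x <- (x - sum(w * x) / sw) / sqrt(sum(w * (x - sum(w * x) / sw)^2) / sw)
    list(x = matrix(x, ncol = 1), y = 0.7 * x + rnorm(50, 0, 0.3), w = w)
  })
  lam <- 20
  f <- fit_weighted_lasso(it$x, it$y, it$w, lam)
  # closed form on weighted-centered data
  sw <- sum(it$w)
  xc <- it$x[, 1] - sum(it$w * it$x[, 1]) / sw
  yc <- it$y - sum(it$w * it$y) / sw
  rho <- sum(it$w * xc * yc)
  closed <- sign(rho) * max(abs(rho) - lam / 2, 0) / sum(it$w * xc^2)
  expect_equal(unname(f$beta), closed, tolerance = 1e-8)
  # independent dense grid search over beta (intercept profiled out)
  grid <- seq(closed - 0.2, closed + 0.2, by = 1e-4)
  obj <- vapply(grid, function(b) {
    b0 <- sum(it$w * (it$y - it$x[, 1] * b)) / sw
    sum(it$w * (it$y - b0 - it$x[, 1] * b)^2) + lam * abs(b)
  }, numeric(1))
  expect_lt(abs(grid[which.min(obj)] - f$beta), 2e-4)
})

test_that("penalty selection is a grid member, prefers accuracy, breaks ties upward", {
  pan <- gwobesity:::with_seed(8, {
    X <- matrix(rnorm(25 * 3), 25)
    list(X = X, y = drop(X %*% c(0.5, -0.4, 0)), w = rep(1, 25))
  })
  # single-element grid
  expect_equal(select_lambda(pan$X, pan$y, pan$w, grid = 0.01)$lambda, 0.01)
  # noiseless linear data: the smallest penalty (zero bias) wins
  sel <- select_lambda(pan$X, pan$y, pan$w, grid = c(0.001, 0.03))
  expect_equal(sel$lambda, 0.001)
  expect_true(sel$loo_error[1] < sel$loo_error[2])
  # membership for a full grid
  g <- default_lambda_grid()
  expect_true(select_lambda(pan$X, pan$y, pan$w, grid = g)$lambda %in% g)
})

test_that("uniform kernel collapses the fit to one global lasso", {
  tr <- synthetic_truth(seed = 41)
  pan <- generate_district_panel(generate_districts(25, seed = 41), tr)
  fitu <- fit_gwlasso(pan, spec = kernel_spec("uniform"))
  # independent global fit on the same standardized design
  X <- as.matrix(pan[, fitu$factors]); w <- rep(1, nrow(pan))
  mu <- colMeans(X); sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  lam <- select_lambda(Xs, pan$y, w, default_lambda_grid())$lambda
  g <- fit_weighted_lasso(Xs, pan$y, w, lam)
  expect_lt(max(abs(sweep(fitu$beta, 2, g$beta))), 1e-8)
  expect_true(all(fitu$lambda == lam))
})

test_that("constant surfaces at zero noise are recovered within 0.02", {
  tr <- synthetic_truth(
    district_surfaces = list(a = function(u, v) rep(0.5, length(u)),
                             b = function(u, v) rep(-0.4, length(u)),
                             c = function(u, v) rep(0, length(u))),
    intercept_surface = function(u, v) rep(0.3, length(u)),
    noise_sd = 0, seed = 42)
  pan <- generate_district_panel(generate_districts(25, seed = 42), tr)
  fit <- fit_gwlasso(pan, grid = 0.001)
  expect_lt(max(abs(sweep(fit$beta_raw, 2, c(0.5, -0.4, 0)))), 0.02)
})

test_that("district order permutation permutes the fit identically", {
  tr <- synthetic_truth(seed = 43)
  pan <- generate_district_panel(generate_districts(15, seed = 43), tr)
  fit <- fit_gwlasso(pan, grid = c(0.005, 0.02))
  perm <- gwobesity:::with_seed(1, sample(nrow(pan)))
  fitp <- fit_gwlasso(pan[perm, ], grid = c(0.005, 0.02))
  expect_equal(fitp$beta[pan$district_id, ], fit$beta, tolerance = 1e-12)
  expect_equal(fitp$lambda[match(pan$district_id, pan$district_id[perm])],
               fit$lambda)
})

test_that("every per-district solution satisfies the weighted-lasso KKT conditions", {
  tr <- synthetic_truth(seed = 44)
  pan <- generate_district_panel(generate_districts(20, seed = 44), tr)
  fit <- fit_gwlasso(pan)
  X <- as.matrix(pan[, fit$factors])
  for (i in seq_len(nrow(pan))) {
    Xs <- sweep(sweep(X, 2, fit$center[i, ]), 2, fit$scale[i, ], `/`)
    b0_std <- fit$intercept_raw[i] + sum(fit$beta[i, ] * fit$center[i, ] / fit$scale[i, ])
    kkt <- lasso_kkt_residual(Xs, pan$y, fit$weights[i, ], fit$lambda[i],
                              b0_std, fit$beta[i, ])
    expect_lt(kkt$max_violation, 1e-6)
  }
})

test_that("the active set shrinks monotonically along the penalty path", {
  it <- random_instance(3, n = 25, p = 6)
  lmax <- lasso_lambda_max(it$X, it$y, it$w)
  grid <- default_lambda_grid(0.001, 1.1 * lmax, 25)  # up to full shrinkage
  nz <- vapply(grid, function(l)
    sum(fit_weighted_lasso(it$X, it$y, it$w, l)$beta != 0), integer(1))
  expect_true(all(diff(nz) <= 0))
  expect_equal(nz[length(nz)], 0L)
})

test_that("coefficient summaries partition districts into POS, NEG and zeros", {
  tr <- synthetic_truth(seed = 45)
  pan <- generate_district_panel(generate_districts(25, seed = 45), tr)
  fit <- fit_gwlasso(pan)
  s <- summarize_coefficients(fit)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  zeros <- colSums(fit$beta == 0)
  expect_equal(s$pos + s$neg + unname(zeros[s$feature]), rep(25, nrow(s)))
  # hand-built fits: all negative, and all zero
  fake <- structure(list(beta = matrix(-0.5, 4, 1, dimnames = list(NULL, "f")),
                         beta_raw = matrix(-0.5, 4, 1, dimnames = list(NULL, "f"))),
                    class = "gwlasso_fit")
  sf <- summarize_coefficients(fake)
  expect_equal(unname(unlist(sf[1, c("min", "mean", "max", "pos", "neg")])),
               c(-0.5, -0.5, -0.5, 0, 4))
  fake$beta[] <- 0
  sz <- summarize_coefficients(fake)
  expect_equal(sz$pos + sz$neg, 0)
})
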