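# Independent oracles used across the test files. Each one deliberately
# avoids the code path it checks.

# Explicit normal-equations VIF: regress column j on the others by solving
# X'X b = X'y directly, no lm().
oracle_vif <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    b <- solve(crossprod(Z), crossprod(Z, y))
    rss <- sum((y - Z %*% b)^2)
    tss <- sum((y - mean(y))^2)
    1 / (1 - (1 - rss / tss))
  }, numeric(1))
}

# Weighted least squares closed form (X'WX)^-1 X'Wy with intercept.
oracle_wls <- function(X, y, w) {
  Xi <- cbind(1, as.matrix(X))
  drop(solve(t(Xi) %*% (w * Xi), t(Xi) %*% (w * y)))
}

# Cover-weighted conditional expectation of one parsed tree given the
# features in S (1-based column indices); features outside S are integrated
# out along the cover fractions.
oracle_cond_exp <- function(tr, node, x, S) {
  i <- node + 1L
  if (tr$feature[i] < 0) return(tr$value[i])
  f <- tr$feature[i] + 1L
  if (f %in% S) {
    nxt <- if (x[f] < tr$threshold[i]) tr$yes[i] else tr$no[i]
    return(oracle_cond_exp(tr, nxt, x, S))
  }
  (tr$cover[tr$yes[i] + 1] / tr$cover[i]) *
    oracle_cond_exp(tr, tr$yes[i], x, S) +
  (tr$cover[tr$no[i] + 1] / tr$cover[i]) *
    oracle_cond_exp(tr, tr$no[i], x, S)
}

# Brute-force Shapley values by subset enumeration (feasible for p <= 5).
oracle_shap <- function(tr, x, p) {
  ens_cond <- function(S)
    sum(vapply(tr$roots, function(r) oracle_cond_exp(tr, r, x, S), numeric(1)))
  phi <- numeric(p)
  all_masks <- 0:(2^p - 1)
  for (k in seq_len(p)) {
    for (mask in all_masks[bitwAnd(all_masks, bitwShiftL(1L, k - 1L)) == 0]) {
      S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0)
      m <- length(S)
      wgt <- factorial(m) * factorial(p - m - 1) / factorial(p)
      phi[k] <- phi[k] + wgt * (ens_cond(c(S, k)) - ens_cond(S))
    }
  }
  phi
}

# small labeled data set that is perfectly separable on one feature
make_separable <- function(n, seed) {
  gwobesity:::with_seed(seed, {
    x1 <- rnorm(n)
    data.frame(x1 = x1, x2 = rnorm(n), obese = x1 > 0)
  })
}
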