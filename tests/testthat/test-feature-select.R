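test_that("VIF is 1 for orthogonal columns and Inf for exact duplicates", {
  X <- data.frame(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(unname(compute_vif(X)), c(1, 1), tolerance = 1e-8)
  X$dup <- X$a
  v <- compute_vif(X)
  expect_true(is.infinite(v["a"]) && is.infinite(v["dup"]))
  X$const <- 1
  expect_error(compute_vif(X), "const")
})

test_that("VIF matches the explicit normal-equations oracle on random designs", {
  for (seed in 1:5) {
    X <- gwobesity:::with_seed(seed, {
      Z <- matrix(rnorm(200 * 6), 200)
      # induce correlation through shared latent factors
      L <- matrix(rnorm(200 * 2), 200)
      as.data.frame(Z + L %*% matrix(runif(12, 0.3, 0.9), 2))
    })
    expect_equal(unname(compute_vif(X)), oracle_vif(X), tolerance = 1e-8)
  }
})

test_that("iterative pruning removes exactly one of a duplicate pair", {
  X <- gwobesity:::with_seed(2, as.data.frame(matrix(rnorm(300), 100)))
  names(X) <- c("a", "b", "c")
  X$a_dup <- X$a
  pr <- iterative_vif_prune(X, threshold = 30)
  expect_equal(pr$removal_order, "a")  # first of the tied pair, by position
  expect_true(all(c("a_dup", "b", "c") %in% names(pr$X)))
  expect_true(all(is.finite(pr$vif)))
  # survivors verified by recomputation
  expect_true(all(compute_vif(pr$X) <= 30))
})

test_that("iterative pruning leaves near-orthogonal designs untouched", {
  X <- gwobesity:::with_seed(3, as.data.frame(matrix(rnorm(500 * 5), 500)))
  pr <- iterative_vif_prune(X, threshold = 30)
  expect_length(pr$removal_order, 0)
  expect_identical(pr$X, X)
})

test_that("a deliberately collinear triplet is pruned below the threshold", {
  X <- gwobesity:::with_seed(4, {
    a <- rnorm(300); b <- rnorm(300)
    data.frame(a = a, b = b, c = a + b + rnorm(300, 0, 0.01),
               d = rnorm(300), e = rnorm(300))
  })
  pr <- iterative_vif_prune(X, threshold = 30)
  expect_true(length(pr$removal_order) >= 1)
  expect_true(max(compute_vif(pr$X)) <= 30)
  expect_lte(length(pr$removal_order), ncol(X))  # terminates in <= p steps
  # each removed feature had the maximal VIF at its removal step
  expect_true(all(pr$removed_vif > 30))
})

test_that("OLS screen keeps a perfect predictor and respects alpha", {
  dat <- gwobesity:::with_seed(5, {
    X <- as.data.frame(matrix(rnorm(500 * 6), 500))
    names(X) <- c("signal", paste0("noise", 1:5))
    list(X = X, y = X$signal)
  })
  # an exactly-deterministic response makes lm warn about the perfect fit;
  # the screen's decision is what matters here
  sc <- suppressWarnings(ols_screen(dat$X, dat$y, alpha = 0.05))
  expect_true("signal" %in% sc$kept)
  expect_length(sc$p_values, 6)
  all_kept <- suppressWarnings(ols_screen(dat$X, dat$y, alpha = 1.0))
  expect_identical(all_kept$kept, names(dat$X))
  expect_error(ols_screen(dat$X[1:5, ], dat$y[1:5]), "more rows")
})

test_that("null-response type-I rate of the OLS screen is near alpha", {
  # desk-scale check (200 reps); the full 1,000-rep calibration runs in the
  # acceptance suite
  reject <- gwobesity:::with_seed(6, {
    colSums(t(vapply(1:200, function(i) {
      X <- as.data.frame(matrix(rnorm(200 * 8), 200))
      ols_screen(X, rnorm(200), alpha = 0.05)$p_values <= 0.05
    }, logical(8))))
  })
  rate <- mean(reject / 200)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / (200 * 8)))
})

test_that("combined screening chains VIF pruning into the OLS screen", {
  tr <- synthetic_truth(seed = 7)
  rec <- generate_individual_records(1500, tr)
  feats <- individual_feature_names(rec)
  sc <- screen_features(rec[feats], rec$obese)
  # exactly one of the duplicate pair survives VIF
  dup_pair <- c("weight_control", "weight_control_dup")
  expect_length(intersect(names(sc$vif_report$X), dup_pair), 1)
  # the dominant effect survives everything
  expect_true("body_shape_awareness" %in% names(sc$X))
})
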