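test_that("raw predictor is the session-1 slice, NaN included", {
  v1 <- matrix(c(0.2, NaN, 0.4, 0.1, 0.3, -0.2), 2, 3)
  p <- make_fisher_panel(v1, v1 + 0.05)
  raw <- raw_estimator(p)
  expect_equal(unname(raw$fisher), v1)
  expect_true(is.nan(raw$fisher[2, 1]))
  expect_equal(raw$correlation, tanh(raw$fisher))
})

test_that("mean predictor averages session 1 and replicates it", {
  p <- make_fisher_panel(matrix(c(0.2, 0.4), 2, 1),
                         matrix(c(0.0, 0.0), 2, 1))
  mn <- mean_estimator(p)
  expect_equal(unname(mn$fisher), matrix(0.3, 2, 1))
  # NaN voxels drop out of the mean; all-NaN voxels stay NaN
  v1 <- matrix(c(0.2, NaN, NaN, NaN), 2, 2)
  mn2 <- mean_estimator(make_fisher_panel(v1, v1))
  expect_equal(unname(mn2$fisher[, 1]), c(0.2, 0.2))
  expect_true(all(is.nan(mn2$fisher[, 2])))
  expect_equal(unname(attr(mn2, "n_effective")), c(1L, 0L))
})

test_that("variance components reproduce the hand-worked three-subject case", {
  p <- make_fisher_panel(matrix(c(0.1, 0.2, 0.0), 3, 1),
                         matrix(c(0.3, 0.2, 0.4), 3, 1))
  vc <- variance_components(p)
  expect_equal(vc$D_bar, 0.2)
  expect_equal(vc$var_U, 0.02)
  expect_equal(vc$var_V, 0.01)
  expect_equal(vc$var_X, 0)   # 0.01 - 0.02 clamped at zero
  expect_true(vc$clamped)
  expect_equal(lambda_map(vc)$lambda, 1)
})

test_that("variance components match the brute-force oracle", {
  set.seed(77)
  for (rep in 1:5) {
    I <- sample(3:10, 1); V <- sample(2:50, 1)
    p <- make_fisher_panel(matrix(rnorm(I * V), I, V),
                           matrix(rnorm(I * V), I, V))
    vc <- variance_components(p)
    oracle <- variance_components_loop(p)
    expect_equal(vc$var_U, oracle$var_U, tolerance = 1e-12)
    expect_equal(vc$var_V, oracle$var_V, tolerance = 1e-12)
    expect_equal(vc$var_X, oracle$var_X, tolerance = 1e-12)
  }
})

test_that("perfect retest gives zero error variance and lambda 0", {
  v <- matrix(rnorm(8), 4, 2)
  p <- make_fisher_panel(v, v)
  vc <- variance_components(p)
  expect_equal(vc$var_U, c(0, 0))
  expect_equal(lambda_map(vc)$lambda, c(0, 0))
})

test_that("lambda map has the stated limits, orientation, and guards", {
  vc <- structure(list(var_U = c(0.01, 0, 0.02), var_V = c(0.05, 0.04, 0.02),
                       var_X = c(0.04, 0.04, 0), D_bar = c(0, 0, 0),
                       clamped = c(FALSE, FALSE, TRUE),
                       n_effective = c(5L, 5L, 5L)),
                  class = "variance_components")
  lm <- lambda_map(vc)
  expect_equal(lm$lambda, c(0.2, 0, 1))  # weight on the mean = 1 - ICC
  expect_equal(lm$icc, 1 - lm$lambda)
  expect_equal(lm$source, "estimated")
  fixed <- lambda_map(vc, fixed_lambda = 0.1)
  expect_equal(fixed$lambda, rep(0.1, 3))
  expect_equal(fixed$source, "fixed")
  expect_error(lambda_map(vc, fixed_lambda = 1.2), "\\[0, 1\\]")
  # voxels with too few complete subjects fall back to the fixed default
  vc$var_U[2] <- NA; vc$var_V[2] <- NA; vc$var_X[2] <- NA
  vc$n_effective[2] <- 1L
  expect_equal(lambda_map(vc)$lambda[2], 0.1)
  expect_equal(lambda_map(vc, fallback_lambda = 0.5)$lambda[2], 0.5)
})

test_that("shrinkage is the stated convex combination with exact limits", {
  sim <- generate_fisher_panel(synth_config(12, n_voxels = 40, rng_seed = 17))
  p <- sim$panel
  raw <- raw_estimator(p); mn <- mean_estimator(p)
  vc <- variance_components(p)
  lam0 <- lambda_map(vc, fixed_lambda = 0)
  lam1 <- lambda_map(vc, fixed_lambda = 1)
  expect_identical(unname(shrink(p, lam0)$fisher), unname(raw$fisher))
  expect_identical(unname(shrink(p, lam1)$fisher), unname(mn$fisher))
  # midpoint arithmetic
  ph <- make_fisher_panel(matrix(c(0.2, 0.6), 2, 1), matrix(0, 2, 1))
  lamh <- lambda_map(variance_components(ph), fixed_lambda = 0.5)
  sh <- shrink(ph, lamh)
  expect_equal(unname(sh$fisher[1, 1]), 0.3)
  expect_equal(unname(sh$correlation[1, 1]), tanh(0.3), tolerance = 1e-12)
  # convexity at every voxel
  lam <- lambda_map(variance_components(p))
  shv <- shrink(p, lam)$fisher
  lo <- pmin(raw$fisher, mn$fisher); hi <- pmax(raw$fisher, mn$fisher)
  expect_true(all(shv >= lo - 1e-12 & shv <= hi + 1e-12))
  expect_error(shrink(p, lam0), NA)
  bad <- lam; bad$lambda <- bad$lambda[-1]
  expect_error(shrink(p, bad), "voxel sets differ")
})

test_that("constant panels shrink safely to the common value", {
  p <- make_fisher_panel(matrix(0.4, 5, 3), matrix(0.4, 5, 3))
  expect_silent(vc <- variance_components(p))
  lam <- lambda_map(vc)
  expect_equal(lam$lambda, rep(1, 3))  # both components zero -> lambda 1
  expect_silent(sh <- shrink(p, lam))
  expect_equal(unname(sh$fisher), matrix(0.4, 5, 3))
})

test_that("estimated lambda converges to the generative weight", {
  cfg <- synth_config(200, n_voxels = 500, sigma2_x = 0.04, sigma2_u = 0.01,
                      rng_seed = 42)
  sim <- generate_fisher_panel(cfg)
  lam <- lambda_map(variance_components(sim$panel))
  expect_lt(abs(mean(lam$lambda) - sim$truth$lambda_true), 0.03)
})

test_that("fewer than two subjects or sessions is an error", {
  p <- make_fisher_panel(matrix(0.1, 2, 2), matrix(0.2, 2, 2))
  expect_error(variance_components(p[1, , , drop = FALSE]), ">=2 subjects")
  p3 <- array(0.1, c(3, 3, 2))
  expect_error(variance_components(p3), "2 sessions")
})
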