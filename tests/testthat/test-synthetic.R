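test_that("config validation rejects degenerate designs", {
  expect_error(synth_config(1, n_voxels = 5), "n_subjects")
  expect_error(synth_config(5, n_sessions = 1, n_voxels = 5), "n_sessions")
  expect_error(synth_config(5, n_voxels = 0), "n_voxels")
  expect_error(synth_config(5, n_voxels = 5, n_timepoints = 4), "n_timepoints")
  expect_error(synth_config(5, n_voxels = 5, sigma2_x = -0.1), "sigma2_x")
  expect_error(synth_config(5, n_voxels = 5, sigma2_u = -1), "sigma2_u")
  expect_error(synth_config(5, n_voxels = 3, mu_x = c(0, 1)), "mu_x")
})

test_that("noiseless model-level generator reproduces mu_x exactly", {
  cfg <- synth_config(4, n_voxels = 3, mu_x = c(0.1, -0.2, 0.5),
                      sigma2_x = 0, sigma2_u = 0, rng_seed = 11)
  sim <- generate_fisher_panel(cfg)
  for (j in 1:2)
    expect_equal(unname(sim$panel[, j, ]),
                 matrix(rep(c(0.1, -0.2, 0.5), each = 4), 4, 3))
  expect_equal(sim$truth$lambda_true, 1)  # both variances zero -> convention
})

test_that("identical config and seed give bit-identical panels", {
  cfg <- synth_config(6, n_voxels = 10, rng_seed = 99)
  expect_identical(generate_fisher_panel(cfg), generate_fisher_panel(cfg))
  cfg2 <- synth_config(4, n_voxels = 5, n_timepoints = 12, rng_seed = 99)
  expect_identical(generate_timeseries_panel(cfg2),
                   generate_timeseries_panel(cfg2))
})

test_that("model-level generator has the stated generative moments", {
  # single voxel, many subjects: Var(V) = sigma2_x + sigma2_u = 0.05
  cfg <- synth_config(5000, n_voxels = 1, mu_x = 0.5,
                      sigma2_x = 0.04, sigma2_u = 0.01, rng_seed = 13)
  sim <- generate_fisher_panel(cfg)
  v1 <- sim$panel[, 1, 1]
  v2 <- sim$panel[, 2, 1]
  expect_lt(abs(var(v1) - 0.05), 0.005)
  expect_lt(abs(mean(v1) - 0.5), 0.02)
  # cross-session covariance across subjects recovers sigma2_x
  expect_lt(abs(cov(v1, v2) - 0.04), 0.005)
})

test_that("true_lambda matches the variance-ratio definition and limits", {
  expect_equal(true_lambda(synth_config(5, n_voxels = 3, sigma2_x = 0.04,
                                        sigma2_u = 0.01)),
               rep(0.2, 3))
  expect_equal(true_lambda(synth_config(5, n_voxels = 2, sigma2_x = 0,
                                        sigma2_u = 0.3)),
               rep(1, 2))
  expect_equal(true_lambda(synth_config(5, n_voxels = 2, sigma2_x = 0.2,
                                        sigma2_u = 0)),
               rep(0, 2))
  # time-series mode folds the finite-T sampling variance into the error
  cfg <- synth_config(5, n_voxels = 1, n_timepoints = 74,
                      sigma2_x = 0.04, sigma2_u = 0.01)
  s2u_eff <- 0.01 + 1 / 71
  expect_equal(true_lambda(cfg, mode = "timeseries"),
               s2u_eff / (0.04 + s2u_eff))
})

test_that("null time-series generator has near-zero seed correlations", {
  cfg <- synth_config(8, n_voxels = 20, n_timepoints = 60, mu_x = 0,
                      sigma2_x = 0, sigma2_u = 0, rng_seed = 5)
  sim <- generate_timeseries_panel(cfg)
  expect_true(all(sim$truth$rho == 0))
  r <- vapply(seq_len(20), function(v)
    cor(sim$panel[1, 1, v, ], sim$truth$seed_signal[1, 1, ]), numeric(1))
  expect_lt(abs(mean(r)), 0.1)  # zero-mean sampling noise only
})

test_that("Fisher-Z estimates carry the classical 1/(T-3) sampling variance", {
  cfg <- synth_config(50, n_voxels = 40, n_timepoints = 74, mu_x = 0,
                      sigma2_x = 0, sigma2_u = 0, rng_seed = 21)
  sim <- generate_timeseries_panel(cfg)
  z <- numeric(0)
  for (i in 1:50) for (j in 1:2) {
    r <- as.vector(cor(t(matrix(sim$panel[i, j, , ], 40, 74)),
                       sim$truth$seed_signal[i, j, ]))
    z <- c(z, atanh(r))
  }
  expect_lt(abs(var(z) / (1 / 71) - 1), 0.10)
  expect_lt(abs(mean(z)), 0.01)
})

test_that("time-series generator recovers the generative mean at long T", {
  cfg <- synth_config(100, n_voxels = 1, n_timepoints = 500, mu_x = 0.8,
                      sigma2_x = 0.02, sigma2_u = 0.01, rng_seed = 31)
  sim <- generate_timeseries_panel(cfg)
  z <- numeric(0)
  for (i in 1:100) for (j in 1:2)
    z <- c(z, atanh(cor(sim$panel[i, j, 1, ], sim$truth$seed_signal[i, j, ])))
  expect_lt(abs(mean(z) - 0.8), 0.05)
})

test_that("flat key-value config files round-trip into synth_config", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("n_subjects = 7", "n_voxels = 9", "n_timepoints = 20",
               "mu_x = 0.1 0.2 0.3 0.1 0.2 0.3 0.1 0.2 0.3",
               "sigma2_x = 0.04", "sigma2_u = 0.01", "# a comment",
               "rng_seed = 5"), path)
  cfg <- read_synth_config(path)
  expect_equal(cfg$n_subjects, 7L)
  expect_equal(cfg$mu_x[6], 0.3)
  writeLines("nonsense_key = 1", path)
  expect_error(read_synth_config(path), "unknown key")
})
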