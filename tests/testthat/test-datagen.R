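test_that("build_sigma constructs compound symmetry and rejects non-PD rho", {
  expect_equal(build_sigma(2, 0), diag(2))
  expect_equal(build_sigma(2, 0.5), matrix(c(1, 0.5, 0.5, 1), 2))
  expect_error(build_sigma(3, -1), "positive-definite")
  expect_error(build_sigma(3, -0.5), "positive-definite")  # 1 + 2*(-0.5) = 0
  expect_error(build_sigma(3, 1), "positive-definite")
  ev <- eigen(build_sigma(5, 0.8), only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("sigma_from_snr evaluates the quadratic form", {
  expect_equal(sigma_from_snr(c(1, 0), diag(2), 1), 1)
  # 0.5 * ones(20), compound symmetric rho = 0.25:
  # beta' Sigma beta = 0.25 * (20 + 380 * 0.25) = 28.75; sigma^2 = 28.75 / 0.5
  b <- rep(0.5, 20)
  S <- build_sigma(20, 0.25)
  expect_equal(drop(crossprod(b, S %*% b)), 28.75)  # direct arithmetic oracle
  expect_equal(sigma_from_snr(b, S, 0.5), sqrt(57.5))
  expect_error(sigma_from_snr(b, S, 0), "snr")
  expect_error(sigma_from_snr(rep(0, 3), diag(3), 1), "signal")
})

test_that("gamma_matrix assembles the joint second-moment matrix", {
  expect_equal(gamma_matrix(matrix(1), 2, 1), matrix(c(1, 2, 2, 5), 2))
  G0 <- gamma_matrix(diag(3), rep(0, 3), 2)
  expect_equal(G0, diag(c(1, 1, 1, 4)))
  G <- gamma_matrix(build_sigma(3, 0.5), c(1, 1, 1), 2)
  expect_true(isSymmetric(G))
  expect_true(all(eigen(G, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(gamma_matrix(diag(2), c(1, 1), -1), "sigma")
})

test_that("scenario validation enforces the mixture assumptions", {
  expect_error(scenario_spec("dense_xy", q = 0.3, rho = 0.3), "Exactly one")
  expect_error(scenario_spec("dense_xy", q = 0.3, snr = 1, sigma = 1), "Exactly one")
  expect_error(scenario_spec("dense_xy", q = 1, snr = 1), "outside")
  expect_error(scenario_spec("dense_xy", q = 0.3, snr = 1, rho = -0.5), "positive-definite")
  expect_warning(scenario_spec("dense_xy", q = 0.6, snr = 1), "minority")
  expect_silent(scenario_spec("dense_xy", q = 0.49, snr = 1))
  sp <- scenario_spec("cloud", q = 0.3, sigma = 0.5)
  expect_error(generate_dataset(sp), "generate_cloud_dataset")
})

test_that("generation follows the clean/outlier mixture", {
  sp0 <- scenario_spec("dense_xy", q = 0, snr = 1, rho = 0.2,
                       n_train = 50, n_test = 10, seed = 1)
  d0 <- generate_dataset(sp0)
  expect_false(any(d0$data$is_outlier))

  sp <- scenario_spec("dense_xy", q = 0.3, snr = 1, rho = 0.2,
                      n_train = 1000, n_test = 0, seed = 5)
  d <- generate_dataset(sp)
  k <- sum(d$data$is_outlier)
  expect_lt(abs(k - 300), 3 * sqrt(1000 * 0.3 * 0.7))

  dsp <- generate_dataset(scenario_spec("sparse_xy", q = 0.2, snr = 1,
                                        rho = 0.2, n_train = 20, seed = 2))
  expect_equal(sum(dsp$truth$beta_star != 0), 4)
  expect_equal(dsp$truth$intercept_star, 3)
  expect_equal(dsp$truth$beta_star[1:8],
               c(0.05, 0, 0.006, 0, -0.007, 0, 0.008, 0))

  # bit-reproducibility and clean test split
  d2 <- generate_dataset(sp0)
  expect_identical(d0$data, d2$data)
  expect_identical(d0$test, d2$test)
  expect_false(any(d0$test$is_outlier))
})

test_that("outlier mechanisms shift the stated coordinates", {
  # dense_x: predictors shifted by +N(5e, I), responses clean given x
  sp <- scenario_spec("dense_x", q = 0.4, sigma = 0.1, rho = 0.2,
                      n_train = 4000, n_test = 0, seed = 11)
  d <- generate_dataset(sp)
  X <- as.matrix(d$data[paste0("x", 1:20)])
  out <- d$data$is_outlier
  expect_equal(mean(X[out, ]), 5, tolerance = 0.1)
  expect_equal(mean(X[!out, ]), 0, tolerance = 0.1)
  mu <- d$truth$intercept_star + X %*% d$truth$beta_star
  r <- d$data$y - drop(mu)
  # responses are clean for both components in the *_x families
  expect_lt(abs(mean(r[out])), 4 * 0.1 / sqrt(sum(out)) + 0.01)

  # dense_xy adds +5 sigma to outlier responses
  sp2 <- scenario_spec("dense_xy", q = 0.4, sigma = 0.1, rho = 0.2,
                       n_train = 4000, n_test = 0, seed = 11)
  d2 <- generate_dataset(sp2)
  X2 <- as.matrix(d2$data[paste0("x", 1:20)])
  r2 <- d2$data$y - drop(d2$truth$intercept_star + X2 %*% d2$truth$beta_star)
  expect_equal(mean(r2[d2$data$is_outlier]), 0.5, tolerance = 0.02)
})

test_that("clean draws match the target covariance and SNR", {
  sp <- scenario_spec("dense_xy", q = 0, snr = 0.8, rho = 0.3,
                      n_train = 50000, n_test = 0, seed = 3)
  d <- generate_dataset(sp)
  X <- as.matrix(d$data[paste0("x", 1:20)])
  Sig_hat <- cov(X)
  expect_lt(max(abs(Sig_hat - build_sigma(20, 0.3))), 0.05)
  b <- d$truth$beta_star
  r <- d$data$y - d$truth$intercept_star - drop(X %*% b)
  snr_hat <- drop(crossprod(b, Sig_hat %*% b)) / var(r)
  expect_equal(snr_hat, 0.8, tolerance = 0.1 * 0.8)
})

test_that("cloud outliers sit in a tight cube exactly delta_r off the plane", {
  d <- generate_cloud_dataset(500, q = 0.3, sigma = 0.5, delta_r = 2.5, seed = 8)
  X <- as.matrix(d$data[paste0("x", 1:30)])
  out <- d$data$is_outlier
  spread <- apply(X[out, , drop = FALSE], 1, function(z) max(z) - min(z))
  expect_true(all(spread <= 0.25))
  off <- d$data$y[out] - (0.3 + 0.5 * rowSums(X[out, , drop = FALSE]))
  expect_equal(off, rep(2.5, sum(out)))

  # q = 0: residuals about the plane are Gaussian noise
  d0 <- generate_cloud_dataset(500, q = 0, sigma = 0.5, delta_r = 2.5, seed = 8)
  X0 <- as.matrix(d0$data[paste0("x", 1:30)])
  r0 <- d0$data$y - (0.3 + 0.5 * rowSums(X0))
  expect_gt(shapiro.test(r0)$p.value, 0.01)
  expect_equal(sd(r0), 0.5, tolerance = 0.1)
  expect_warning(generate_cloud_dataset(20, q = 0.6, sigma = 1, delta_r = 1),
                 "minority")
})
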