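test_that("wdro_objective matches its term-by-term definition", {
  set.seed(1)
  for (k in 1:20) {
    d <- rand_reg_df(12, 3, seed = k)
    beta <- rnorm(3); b0 <- rnorm(1); eps <- runif(1)
    X <- as.matrix(d[paste0("x", 1:3)])
    for (kind in c("l1", "l2", "linf")) {
      manual <- mean(abs(d$y - b0 - X %*% beta)) + eps * kappa_oracle(kind, beta)
      expect_equal(wdro_objective(d, beta, b0, eps, kind), manual,
                   tolerance = 1e-12)
    }
  }
  # zero-coefficient case: mean |y| + eps (kappa(0) = 1)
  d <- rand_reg_df(10, 2, seed = 99)
  expect_equal(wdro_objective(d, c(0, 0), 0, 0.3, "l2"),
               mean(abs(d$y)) + 0.3)
})

test_that("exact interpolation with the penalty off", {
  d <- data.frame(x1 = c(1, 2), y = c(1, 2))
  f <- fit_wdro(d, epsilon = 0, intercept = FALSE)
  expect_equal(f$beta, c(x1 = 1), tolerance = 1e-8)
  expect_equal(f$objective, 0, tolerance = 1e-9)
})

test_that("small hand-checked DRO optima (subgradient oracle)", {
  d <- data.frame(x1 = c(1, -1), y = c(1, -1))
  # sup-norm metric, eps = 2: penalty slope 2 beats loss slope 1, beta = 0
  f <- fit_wdro(d, epsilon = 2, norm = "linf", intercept = FALSE)
  expect_equal(f$objective, 3, tolerance = 1e-7)
  expect_equal(unname(f$beta), 0, tolerance = 1e-7)
  # l2 metric, eps = 0.1: loss slope -1 dominates until beta = 1
  f2 <- fit_wdro(d, epsilon = 0.1, norm = "l2", intercept = FALSE)
  expect_equal(unname(f2$beta), 1, tolerance = 1e-5)
  expect_equal(f2$objective, 0.1 * sqrt(2), tolerance = 1e-7)
})

test_that("solver optimum matches dense grid search for every metric", {
  set.seed(5)
  M3 <- crossprod(matrix(rnorm(9), 3)) / 3 + diag(3)
  M2 <- crossprod(matrix(rnorm(4), 2)) / 2 + diag(2)
  for (k in 1:15) {
    p <- sample(1:2, 1)
    d <- rand_reg_df(sample(5:10, 1), p, seed = 100 + k, noise = 0.5)
    X <- as.matrix(d[paste0("x", seq_len(p))])
    eps <- runif(1, 0.01, 0.8)
    for (kind in c("l1", "l2", "linf", "weighted")) {
      M <- if (kind == "weighted") (if (p == 1) M2 else M3) else NULL
      f <- fit_wdro(d, epsilon = eps, norm = kind, M = M, intercept = FALSE)
      gmin <- grid_min_wdro(X, d$y, eps, kind,
                            Minv = if (!is.null(M)) solve(M))
      expect_lt(abs(f$objective - gmin), 1e-4)
      expect_gte(gmin - f$objective, -1e-4)  # never above the solver optimum
    }
  }
})

test_that("the reported objective is the objective at the returned point", {
  set.seed(6)
  for (kind in c("l1", "l2", "linf")) {
    d <- rand_reg_df(30, 4, seed = 7)
    f <- fit_wdro(d, epsilon = 0.2, norm = kind)
    expect_equal(f$objective,
                 wdro_objective(d, f$beta, f$intercept, 0.2, kind),
                 tolerance = 1e-6)
  }
})

test_that("LAD fits a median and coincides with the radius-zero DRO fit", {
  d <- data.frame(x1 = c(0, 0, 0), y = c(-1, 0, 1))
  f <- fit_lad(d)
  expect_equal(f$intercept, 0, tolerance = 1e-8)

  dlin <- data.frame(x1 = 1:5, y = 2 * (1:5) + 3)
  expect_equal(fit_lad(dlin)$objective, 0, tolerance = 1e-8)

  for (k in 1:100) {
    d <- rand_reg_df(sample(8:25, 1), sample(1:4, 1), seed = 200 + k)
    f1 <- fit_lad(d)
    f2 <- fit_wdro(d, epsilon = 0, norm = sample(c("l1", "l2", "linf"), 1))
    expect_lt(abs(f1$objective - f2$objective), 1e-8)
  }
})

test_that("interior-point LAD agrees with the simplex oracle", {
  set.seed(31)
  for (k in 1:15) {
    N <- sample(c(20, 50, 80), 1); p <- sample(c(1, 3, 8, 15), 1)
    d <- rand_reg_df(N, p, seed = 300 + k, xmean = sample(c(0, 5), 1),
                     noise = runif(1, 0.1, 3))
    lam <- sample(c(0, 0.05, 0.5), 1)
    f <- if (lam == 0) fit_lad(d) else fit_regularized_lad(d, "l1", lam)
    X <- as.matrix(d[paste0("x", seq_len(p))])
    A3 <- cbind(X, -X, 1, -1, diag(N), -diag(N))
    a <- c(rep(lam, 2 * p), 0, 0, rep(1 / N, 2 * N))
    s <- boot::simplex(a = a, A3 = A3, b3 = d$y, maxi = FALSE, n.iter = 4000)
    expect_equal(f$objective, unname(s$value), tolerance = 1e-7)
  }
})

test_that("the sup-norm DRO objective is the l1-penalized LAD plus epsilon", {
  set.seed(8)
  for (k in 1:10) {
    d <- rand_reg_df(sample(10:30, 1), sample(2:5, 1), seed = 400 + k)
    eps <- runif(1, 0.02, 0.5)
    f1 <- fit_wdro(d, epsilon = eps, norm = "linf")
    f2 <- fit_regularized_lad(d, "l1", lambda = eps)
    expect_equal(f1$objective - f2$objective, eps, tolerance = 1e-6)
  }
})

test_that("regularized LAD limits: lambda 0 is LAD; huge l2 penalty zeroes beta", {
  d <- rand_reg_df(20, 3, seed = 9)
  expect_equal(fit_regularized_lad(d, "l1", 0)$objective,
               fit_lad(d)$objective, tolerance = 1e-9)
  X <- as.matrix(d[paste0("x", 1:3)])
  lam_big <- 2 * max(sqrt(rowSums(X^2)))
  fz <- fit_regularized_lad(d, "l2", lam_big)
  expect_identical(unname(fz$beta), rep(0, 3))
  expect_equal(fz$intercept, median(d$y))
})

test_that("regularization path: loss grows and penalty shrinks with epsilon", {
  d <- rand_reg_df(40, 3, seed = 10, noise = 0.8)
  X <- as.matrix(d[paste0("x", 1:3)])
  eps_grid <- exp(seq(log(1e-3), log(2), length.out = 20))
  loss <- kap <- numeric(20)
  for (i in seq_along(eps_grid)) {
    f <- fit_wdro(d, epsilon = eps_grid[i], norm = "l2")
    loss[i] <- mean(abs(d$y - f$intercept - X %*% f$beta))
    kap[i] <- dual_norm("l2", f$beta)
  }
  expect_true(all(diff(loss) >= -1e-7))
  expect_true(all(diff(kap) <= 1e-7))
})

test_that("identity weighting reproduces the l2 metric exactly", {
  set.seed(11)
  for (k in 1:5) {
    d <- rand_reg_df(30, 4, seed = 500 + k)
    f1 <- fit_wdro(d, epsilon = 0.3, norm = "l2")
    f2 <- fit_wdro(d, epsilon = 0.3, norm = "weighted", M = diag(5))
    expect_lt(abs(f1$objective - f2$objective), 1e-8)
    expect_lt(max(abs(f1$beta - f2$beta)), 1e-6)
  }
})

test_that("response-weight c to infinity recovers the l2-penalized LAD", {
  set.seed(12)
  for (k in 1:4) {
    d <- rand_reg_df(25, 3, seed = 600 + k, noise = 1.5)
    freg <- fit_regularized_lad(d, "l2", lambda = 0.3)
    dist <- vapply(c(1, 10, 100, 1000), function(cc) {
      M <- diag(c(rep(1, 3), cc^2))
      fw <- fit_wdro(d, epsilon = 0.3, norm = "weighted", M = M)
      sqrt(sum((fw$beta - freg$beta)^2))
    }, numeric(1))
    expect_true(all(diff(dist) <= 1e-9))
  }
})

test_that("the l1-ball constraint binds and relaxes correctly", {
  d <- rand_reg_df(30, 3, seed = 13, beta = c(2, -2, 1), noise = 0.1)
  # LP route
  f <- fit_wdro(d, epsilon = 0.05, norm = "linf", l1_ball = 1.5)
  expect_lte(sum(abs(f$beta)), 1.5 + 1e-7)
  f_loose <- fit_wdro(d, epsilon = 0.05, norm = "linf", l1_ball = 1e4)
  f_free <- fit_wdro(d, epsilon = 0.05, norm = "linf")
  expect_equal(f_loose$objective, f_free$objective, tolerance = 1e-7)
  # conic route (Lagrangian bisection)
  g <- fit_wdro(d, epsilon = 0.05, norm = "l2", l1_ball = 1.5)
  expect_lte(sum(abs(g$beta)), 1.5 + 1e-7)
  g_free <- fit_wdro(d, epsilon = 0.05, norm = "l2")
  expect_gte(g$objective, g_free$objective - 1e-8)
  g_loose <- fit_wdro(d, epsilon = 0.05, norm = "l2", l1_ball = 1e4)
  expect_equal(g_loose$objective, g_free$objective, tolerance = 1e-7)
})

test_that("estimation error shrinks from N = 100 to N = 2000 on clean data", {
  errs <- sapply(1:6, function(r) {
    sapply(c(100, 2000), function(N) {
      sp <- scenario_spec("dense_xy", q = 0, snr = 2, rho = 0.3,
                          n_train = N, n_test = 0, seed = 700 + r)
      ds <- generate_dataset(sp)
      f <- fit_wdro(drop_labels(ds$data), epsilon = 0.01, norm = "l2")
      sqrt(sum((f$beta - ds$truth$beta_star)^2))
    })
  })
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})
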