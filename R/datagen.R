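#' Compound-symmetric predictor covariance
#'
#' Builds the equicorrelation matrix with unit diagonal and constant
#' off-diagonal correlation `rho`, the predictor covariance used throughout
#' the synthetic benchmark. Its eigenvalues are \eqn{1 + (p-1)\rho} (once)
#' and \eqn{1 - \rho} (p-1 times), so positive definiteness requires
#' \eqn{\rho \in (-1/(p-1), 1)}.
#'
#' @param p Number of predictors.
#' @param rho Common correlation.
#' @return A `p` x `p` positive-definite matrix.
#' @export
build_sigma <- function(p, rho) {
  p <- check_count(p, "p")
  check_number(rho, "rho")
  lo <- if (p > 1) -1 / (p - 1) else -Inf
  if (rho <= lo || rho >= 1) {
    stop_wdrolad(paste0(
      "rho = %g gives a non-positive-definite compound-symmetric matrix; ",
      "need rho in (%g, 1) for p = %d (eigenvalues 1 + (p-1)rho and 1 - rho)."),
      rho, lo, p)
  }
  S <- matrix(rho, p, p)
  diag(S) <- 1
  S
}

#' Noise standard deviation implied by a signal-to-noise ratio
#'
#' The signal-to-noise ratio of the generating model is
#' \eqn{SNR = \beta^{*\prime} \Sigma \beta^* / \sigma^2}; given a target SNR
#' this returns \eqn{\sigma = \sqrt{\beta^{*\prime}\Sigma\beta^* / SNR}}.
#'
#' @param beta_star True coefficient vector.
#' @param Sigma Predictor covariance.
#' @param snr Target signal-to-noise ratio (> 0).
#' @return Positive scalar sigma.
#' @export
sigma_from_snr <- function(beta_star, Sigma, snr) {
  check_number(snr, "snr", lower = 0, strict_lower = TRUE)
  beta_star <- as.numeric(beta_star)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != length(beta_star)) {
    stop_wdrolad("`Sigma` must be %d x %d.", length(beta_star), length(beta_star))
  }
  sig2 <- drop(crossprod(beta_star, Sigma %*% beta_star))
  if (sig2 <= 0) stop_wdrolad("`beta_star` carries no signal (beta'Sigma beta = 0).")
  sqrt(sig2 / snr)
}

#' Second-moment matrix of the joint vector (x, y)
#'
#' Assembles \eqn{\Gamma = E[(x,y)(x,y)']} for the centred generating model:
#' the block matrix with \eqn{\Sigma} and cross-covariance
#' \eqn{\Sigma\beta^*} on the off-diagonal block, and
#' \eqn{\beta^{*\prime}\Sigma\beta^* + \sigma^2} in the response corner.
#'
#' @inheritParams sigma_from_snr
#' @param sigma Noise standard deviation (> 0).
#' @return Symmetric positive-semidefinite matrix of dimension
#'   `length(beta_star) + 1`.
#' @export
gamma_matrix <- function(Sigma, beta_star, sigma) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  beta_star <- as.numeric(beta_star)
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != length(beta_star)) {
    stop_wdrolad("`Sigma` must be %d x %d.", length(beta_star), length(beta_star))
  }
  sb <- drop(Sigma %*% beta_star)
  G <- rbind(cbind(Sigma, sb),
             c(sb, drop(crossprod(beta_star, sb)) + sigma^2))
  dimnames(G) <- NULL
  G
}

#' Generating ground truth
#'
#' @param beta_star True coefficients.
#' @param intercept_star True intercept.
#' @param sigma Noise standard deviation (> 0).
#' @param Sigma Predictor covariance (symmetric positive definite).
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(beta_star, intercept_star, sigma, Sigma) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(intercept_star, "intercept_star")
  beta_star <- as.numeric(beta_star)
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(Sigma, tol = 1e-8)) stop_wdrolad("`Sigma` must be symmetric.")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_wdrolad("`Sigma` must be positive definite (min eigenvalue %.3g).", min(ev))
  }
  structure(list(beta_star = beta_star, intercept_star = intercept_star,
                 sigma = sigma, Sigma = Sigma),
            class = "ground_truth")
}

# Fixed true coefficients per scenario family
family_truth <- function(family) {
  if (family %in% c("dense_xy", "dense_x")) {
    list(beta = rep(0.5, 20), intercept = 0.3)
  } else if (family %in% c("sparse_xy", "sparse_x")) {
    list(beta = c(0.05, 0, 0.006, 0, -0.007, 0, 0.008, rep(0, 13)),
         intercept = 3)
  } else {
    stop_wdrolad("Unknown scenario family `%s`.", family)
  }
}

#' Describe one synthetic contaminated-regression scenario
#'
#' Each training sample is drawn from the clean distribution
#' (\eqn{x \sim N(0, \Sigma)} with compound-symmetric \eqn{\Sigma},
#' \eqn{y \sim N(\beta_0^* + x'\beta^*, \sigma^2)}) with probability
#' \eqn{1-q}, and from the family's outlying distribution otherwise.
#' Families: `dense_xy` / `dense_x` use the dense truth (intercept 0.3, all
#' twenty coefficients 0.5) with the predictor shift \eqn{+N(5e, I)} and, for
#' `dense_xy`, a \eqn{+5\sigma} response shift; `sparse_xy` / `sparse_x` use
#' the sparse truth (intercept 3, four nonzero coefficients) with predictor
#' perturbation \eqn{+N(0, 0.25 I)} and \eqn{+5\sigma} response shift
#' (`sparse_xy`) or the \eqn{+N(5e, I)} predictor shift with a clean response
#' (`sparse_x`). The `cloud` family is handled by
#' [generate_cloud_dataset()].
#'
#' @param family One of `"dense_xy"`, `"dense_x"`, `"sparse_xy"`,
#'   `"sparse_x"`, `"cloud"`.
#' @param q Contamination probability in \code{[0, 1)}. Outliers are assumed
#'   to be the minority; `q >= 0.5` is allowed but triggers a warning.
#' @param snr,sigma Exactly one of the signal-to-noise ratio or the noise
#'   standard deviation must be supplied.
#' @param rho Predictor correlation, inside the positive-definite range of
#'   the compound-symmetric covariance.
#' @param n_train,n_test Training and (clean-only) test sample sizes.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(family, q, snr = NULL, sigma = NULL, rho = 0.3,
                          n_train = 100, n_test = 60, seed = 1) {
  family <- match.arg(family, c("dense_xy", "dense_x", "sparse_xy",
                                "sparse_x", "cloud"))
  check_number(q, "q", lower = 0, upper = 1, strict_upper = TRUE)
  if (q >= 0.5) {
    warn(sprintf("q = %g: outliers are assumed to be the minority (q < 0.5).", q))
  }
  if (is.null(snr) == is.null(sigma)) {
    stop_wdrolad("Exactly one of `snr` and `sigma` must be given.")
  }
  if (!is.null(snr)) check_number(snr, "snr", lower = 0, strict_lower = TRUE)
  if (!is.null(sigma)) check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  n_train <- check_count(n_train, "n_train")
  n_test <- check_count(n_test, "n_test", lower = 0L)
  seed <- check_count(seed, "seed", lower = 0L)
  if (family != "cloud") {
    p <- length(family_truth(family)$beta)
    lo <- -1 / (p - 1)
    if (rho <= lo || rho >= 1) {
      stop_wdrolad("rho = %g outside the positive-definite range (%g, 1).", rho, lo)
    }
  }
  structure(list(family = family, q = q, snr = snr, sigma = sigma, rho = rho,
                 n_train = n_train, n_test = n_test, seed = seed),
            class = "scenario_spec")
}

#' Generate a contaminated regression dataset
#'
#' Draws a training set from the clean/outlying mixture described by the
#' scenario (one uniform draw decides each sample's component) and a test set
#' from the clean distribution only. The generating truth is attached.
#'
#' @param spec A [scenario_spec()].
#' @return A `regression_data` object: list with `data` (training tibble with
#'   predictor columns `x1..xp`, response `y` and logical `is_outlier`),
#'   `test` (clean-only tibble), `truth` (a [ground_truth()]), and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$family == "cloud") {
    stop_wdrolad("Use generate_cloud_dataset() for the `cloud` family.")
  }
  tr <- family_truth(spec$family)
  p <- length(tr$beta)
  Sigma <- build_sigma(p, spec$rho)
  sigma <- spec$sigma %||% sigma_from_snr(tr$beta, Sigma, spec$snr)
  truth <- ground_truth(tr$beta, tr$intercept, sigma, Sigma)

  set.seed(spec$seed)
  n <- spec$n_train
  CS <- chol(Sigma)
  is_out <- runif(n) > (1 - spec$q)

  X <- matrix(rnorm(n * p), n, p) %*% CS
  if (any(is_out)) {
    k <- sum(is_out)
    shift <- switch(spec$family,
      dense_xy = ,
      dense_x = ,
      sparse_x = matrix(rnorm(k * p, mean = 5), k, p),
      sparse_xy = matrix(rnorm(k * p, sd = 0.5), k, p))
    X[is_out, ] <- X[is_out, , drop = FALSE] + shift
  }
  y <- truth$intercept_star + drop(X %*% truth$beta_star) + sigma * rnorm(n)
  if (spec$family %in% c("dense_xy", "sparse_xy")) {
    y[is_out] <- y[is_out] + 5 * sigma
  }

  test <- NULL
  if (spec$n_test > 0) {
    Xt <- matrix(rnorm(spec$n_test * p), spec$n_test, p) %*% CS
    yt <- truth$intercept_star + drop(Xt %*% truth$beta_star) +
      sigma * rnorm(spec$n_test)
    test <- as_reg_tibble(Xt, yt, rep(FALSE, spec$n_test))
  }

  new_regression_data(as_reg_tibble(X, y, is_out), test, truth, spec)
}

#' Generate the outlier-cloud detection dataset
#'
#' Clean samples have thirty i.i.d. predictors \eqn{N(7.5, 4^2)} and response
#' \eqn{y = 0.3 + 0.5\sum_j x_j + N(0, \sigma^2)}. Outliers form a tight
#' cloud: a single centre \eqn{u \sim U(7.5 - 12, 7.5 + 12)} is drawn per
#' outlier, its predictors are i.i.d. \eqn{U(u - 0.125, u + 0.125)}, and the
#' response sits exactly at distance `delta_r` off the true regression plane:
#' \eqn{y = 0.3 + 0.5\sum_j x_j + \delta_R}.
#'
#' @param n Sample size.
#' @param q Contamination probability in \code{[0, 1)}.
#' @param sigma Clean-noise standard deviation.
#' @param delta_r Response offset of the outlier cloud.
#' @param seed Integer seed.
#' @return A `regression_data` object (no test split; generate a second
#'   dataset with a different seed for out-of-sample evaluation).
#' @export
generate_cloud_dataset <- function(n, q, sigma, delta_r, seed = 1) {
  n <- check_count(n, "n")
  check_number(q, "q", lower = 0, upper = 1, strict_upper = TRUE)
  if (q >= 0.5) {
    warn(sprintf("q = %g: outliers are assumed to be the minority (q < 0.5).", q))
  }
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(delta_r, "delta_r")
  p <- 30L
  truth <- ground_truth(rep(0.5, p), 0.3, sigma, diag(16, p))

  set.seed(seed)
  is_out <- runif(n) > (1 - q)
  X <- matrix(rnorm(n * p, mean = 7.5, sd = 4), n, p)
  if (any(is_out)) {
    k <- sum(is_out)
    u <- runif(k, 7.5 - 12, 7.5 + 12)
    X[is_out, ] <- matrix(runif(k * p, -0.125, 0.125), k, p) + u
  }
  y <- 0.3 + 0.5 * rowSums(X) + sigma * rnorm(n)
  y[is_out] <- 0.3 + 0.5 * rowSums(X[is_out, , drop = FALSE]) + delta_r

  spec <- structure(list(family = "cloud", q = q, sigma = sigma,
                         delta_r = delta_r, n_train = n, n_test = 0L,
                         seed = seed),
                    class = "scenario_spec")
  new_regression_data(as_reg_tibble(X, y, is_out), NULL, truth, spec)
}

as_reg_tibble <- function(X, y, is_out = NULL) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  out <- tibble::as_tibble(as.data.frame(X))
  out$y <- as.numeric(y)
  if (!is.null(is_out)) out$is_outlier <- as.logical(is_out)
  out
}

new_regression_data <- function(data, test, truth, spec) {
  structure(list(data = data, test = test, truth = truth, spec = spec),
            class = "regression_data")
}

#' @export
print.regression_data <- function(x, ...) {
  cat(sprintf("<regression_data> family=%s  n_train=%d  n_test=%d  outliers=%d\n",
              x$spec$family, nrow(x$data),
              if (is.null(x$test)) 0L else nrow(x$test),
              sum(x$data$is_outlier %||% FALSE)))
  invisible(x)
}
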