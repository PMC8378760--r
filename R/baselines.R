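#' Squared-residual baseline estimators
#'
#' Ordinary least squares and its penalized variants, minimizing
#' \eqn{\frac1N \sum_i (y_i - \beta_0 - x_i'\beta)^2 + \lambda P(\beta)} with
#' \eqn{P = \|\beta\|_2^2} (ridge), \eqn{\|\beta\|_1} (lasso) or
#' \eqn{\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2} (elastic net); the
#' intercept is unpenalized. OLS and ridge use exact linear algebra (OLS on a
#' rank-deficient design returns the minimum-norm solution); lasso and
#' elastic net are delegated to \pkg{glmnet} with the objective
#' reparameterized accordingly.
#'
#' @inheritParams fit_wdro
#' @param kind One of `"ols"`, `"ridge"`, `"lasso"`, `"en"`.
#' @param lambda Penalty weight (>= 0); ignored for `"ols"`.
#' @param alpha Elastic-net mixing weight in \code{[0, 1]} (used for
#'   `kind = "en"` only).
#' @return A `wdrolad_fit`; `objective` is the penalized mean squared
#'   residual.
#' @export
fit_sr_baseline <- function(data, kind = c("ols", "ridge", "lasso", "en"),
                            lambda = 0, alpha = 0.5, intercept = TRUE,
                            response = "y") {
  kind <- match.arg(kind)
  check_number(lambda, "lambda", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  xy <- as_xy(data, response)
  X <- xy$X; y <- xy$y; N <- nrow(X); p <- ncol(X)
  if (kind == "ols") lambda <- 0

  if (kind %in% c("ols", "ridge")) {
    if (intercept) {
      xbar <- colMeans(X); ybar <- mean(y)
      Xc <- sweep(X, 2, xbar); yc <- y - ybar
    } else {
      Xc <- X; yc <- y
    }
    if (lambda == 0) {
      qrX <- qr(Xc)
      if (qrX$rank < p) {
        # minimum-norm least-squares solution on a rank-deficient design
        sv <- svd(Xc)
        pos <- sv$d > max(sv$d) * 1e-12
        beta <- drop(sv$v[, pos, drop = FALSE] %*%
                       ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos]))
      } else {
        beta <- qr.coef(qrX, yc)
      }
    } else {
      beta <- drop(solve(crossprod(Xc) / N + lambda * diag(p), crossprod(Xc, yc) / N))
    }
    b0 <- if (intercept) ybar - sum(xbar * beta) else 0
  } else if (p == 1L) {
    # closed-form soft-thresholding; glmnet needs >= 2 predictor columns
    if (intercept) {
      xbar <- mean(X); ybar <- mean(y)
      Xc <- X - xbar; yc <- y - ybar
    } else { Xc <- X; yc <- y }
    a <- if (kind == "lasso") 1 else alpha
    z <- sum(Xc * yc) / N
    beta <- soft_threshold(z, lambda * a / 2) / (sum(Xc^2) / N + lambda * (1 - a))
    b0 <- if (intercept) ybar - mean(X) * beta else 0
  } else {
    # glmnet (user-supplied lambda, gaussian) effectively penalizes
    # lam_g * a_g * ||b||_1 + lam_g (1 - a_g) / (2 s_y) * ||b||_2^2 on the
    # (1/(2N))RSS scale, where s_y = sd(y) with denominator N (the response
    # is standardized internally). Matching
    # (1/N)RSS + lambda (a ||b||_1 + (1-a) ||b||_2^2) therefore requires
    # lam_g a_g = lambda a / 2 and lam_g (1 - a_g) = lambda (1 - a) s_y.
    a <- if (kind == "lasso") 1 else alpha
    s_y <- sqrt(var(y) * (N - 1) / N)
    lam_g <- lambda * a / 2 + lambda * (1 - a) * s_y
    a_g <- (lambda * a / 2) / lam_g
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = a_g,
                          lambda = lam_g * c(16, 8, 4, 2, 1),
                          standardize = FALSE, intercept = intercept,
                          thresh = 1e-14, maxit = 10^6)
    cf <- coef(fit, s = lam_g)  # lam_g is on the supplied path: no interpolation
    beta <- as.numeric(cf)[-1]
    b0 <- as.numeric(cf)[1]
  }

  r <- y - b0 - drop(X %*% beta)
  pen <- switch(kind, ols = 0, ridge = sum(beta^2),
                lasso = sum(abs(beta)),
                en = alpha * sum(abs(beta)) + (1 - alpha) * sum(beta^2))
  new_fit_result(beta, b0, mean(r^2) + lambda * pen, status = "optimal",
                 method = kind,
                 solver_meta = list(lambda = lambda,
                                    alpha = if (kind == "en") alpha else NULL),
                 xnames = xy$xnames)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' IRLS weight functions for M-estimation
#'
#' Weights applied to each observation given its scaled residual `u`:
#' Huber `min(1, 1/|u|)`, Talwar (hard rejection) `1(|u| <= 1)`, and Fair
#' `1/(1 + |u|)`. All are 1 at `u = 0` and lie in \code{[0, 1]}.
#'
#' @param psi One of `"huber"`, `"talwar"`, `"fair"`.
#' @param u Numeric vector of scaled residuals.
#' @return Weight vector in \code{[0, 1]}.
#' @export
irls_weights <- function(psi = c("huber", "talwar", "fair"), u) {
  psi <- match.arg(psi)
  u <- abs(as.numeric(u))
  if (anyNA(u)) stop_wdrolad("`u` contains missing values.")
  switch(psi,
    huber = ifelse(u <= 1, 1, 1 / u),
    talwar = as.numeric(u <= 1),
    fair = 1 / (1 + u)
  )
}

#' Robust regression by iteratively reweighted least squares
#'
#' Classical M-estimation: starting from OLS, residuals are rescaled by a
#' robust scale estimate (median absolute deviation about the median,
#' divided by 0.6745, re-estimated every iteration) and a tuning constant,
#' converted into weights by [irls_weights()], and a weighted least-squares
#' refit is performed until the coefficients stabilize.
#'
#' @inheritParams fit_wdro
#' @param psi Weight family: `"huber"`, `"talwar"` or `"fair"`.
#' @param tuning_const Positive tuning constant; defaults to the classical
#'   95%-efficiency values 1.345 (Huber), 2.795 (Talwar), 1.4 (Fair).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence threshold on the maximum coefficient change.
#' @return A `wdrolad_fit`; `solver_meta` records iterations, convergence
#'   and the final weights. `objective` is the mean absolute residual (for
#'   reporting only; the estimator is defined by its fixed point).
#' @export
fit_mestimator <- function(data, psi = c("huber", "talwar", "fair"),
                           tuning_const = NULL, max_iter = 50L, tol = 1e-6,
                           intercept = TRUE, response = "y") {
  psi <- match.arg(psi)
  tuning_const <- tuning_const %||%
    switch(psi, huber = 1.345, talwar = 2.795, fair = 1.4)
  check_number(tuning_const, "tuning_const", lower = 0, strict_lower = TRUE)
  max_iter <- check_count(max_iter, "max_iter")
  check_number(tol, "tol", lower = 0, strict_lower = TRUE)
  xy <- as_xy(data, response)
  X <- xy$X; y <- xy$y; N <- nrow(X); p <- ncol(X)
  if (N <= p + as.integer(intercept)) {
    stop_wdrolad("IRLS needs more observations than coefficients (N = %d, p = %d).",
                 N, p + as.integer(intercept))
  }
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X

  cf <- qr.coef(qr(Xd), y)
  cf[is.na(cf)] <- 0
  w <- rep(1, N)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    r <- y - drop(Xd %*% cf)
    s_hat <- median(abs(r - median(r))) / 0.6745
    if (s_hat == 0) { converged <- TRUE; break }
    u <- r / (tuning_const * s_hat)
    w <- irls_weights(psi, u)
    if (sum(w > 0) <= ncol(Xd)) w <- pmax(w, 1e-8)
    fitw <- stats::lm.wfit(Xd, y, w = w)
    cf_new <- fitw$coefficients
    cf_new[is.na(cf_new)] <- 0
    delta <- max(abs(cf_new - cf))
    cf <- cf_new
    if (delta < tol) { converged <- TRUE; break }
  }
  beta <- if (intercept) cf[-1] else cf
  b0 <- if (intercept) cf[1] else 0
  r <- y - b0 - drop(X %*% beta)
  new_fit_result(beta, b0, mean(abs(r)),
                 status = if (converged) "optimal" else "numerical_failure",
                 method = paste0("m_", psi),
                 solver_meta = list(psi = psi, tuning_const = tuning_const,
                                    iterations = iters, converged = converged,
                                    weights = w),
                 xnames = xy$xnames)
}
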