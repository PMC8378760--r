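#' Out-of-sample generalization bound
#'
#' With probability at least `1 - delta` over the sampling, the expected
#' absolute loss of the fitted coefficients on new data is at most
#' \deqn{\frac1N\sum_i |y_i - x_i'\hat\beta| + \frac{2\bar B R}{\sqrt N} +
#'   \bar B R \sqrt{\frac{8\log(2/\delta)}{N}},}
#' where `R` bounds \eqn{\|(x, y)\|} almost surely and \eqn{\bar B} bounds
#' the dual norm \eqn{\|(-\beta,1)\|_*} over the feasible set. Logarithms are
#' natural.
#'
#' @param avg_loss Training mean absolute residual (>= 0).
#' @param b_bar Dual-norm bound \eqn{\bar B} (> 0).
#' @param r Data-norm bound `R` (> 0).
#' @param n Sample size.
#' @param delta Confidence parameter in (0, 1).
#' @return Scalar upper bound on the expected out-of-sample absolute loss.
#' @export
generalization_bound <- function(avg_loss, b_bar, r, n, delta) {
  check_number(avg_loss, "avg_loss", lower = 0)
  check_number(b_bar, "b_bar", lower = 0, strict_lower = TRUE)
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  n <- check_count(n, "n")
  check_number(delta, "delta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  br <- b_bar * r
  avg_loss + 2 * br / sqrt(n) + br * sqrt(8 * log(2 / delta) / n)
}

#' Tail bound on the out-of-sample absolute loss
#'
#' Markov-type bound on the probability that a new sample's absolute loss
#' exceeds the training average by more than `zeta`:
#' \deqn{P(|y - x'\hat\beta| \ge \bar L + \zeta) \le
#'   \frac{\bar L + 2\bar BR/\sqrt N + \bar BR\sqrt{8\log(2/\delta)/N}}
#'        {\bar L + \zeta},}
#' valid (with probability `1 - delta` over the sampling) for any `zeta`
#' strictly above the deviation term
#' \eqn{2\bar BR/\sqrt N + \bar BR\sqrt{8\log(2/\delta)/N}}.
#'
#' @inheritParams generalization_bound
#' @param zeta Exceedance level; must exceed the deviation term.
#' @return Probability bound in \code{[0, 1]}.
#' @export
tail_bound <- function(avg_loss, b_bar, r, n, delta, zeta) {
  check_number(zeta, "zeta", lower = 0, strict_lower = TRUE)
  ub <- generalization_bound(avg_loss, b_bar, r, n, delta)
  dev <- ub - avg_loss
  if (zeta <= dev) {
    stop_wdrolad(paste0(
      "`zeta` = %g does not satisfy the precondition zeta > ",
      "2*b_bar*r/sqrt(n) + b_bar*r*sqrt(8*log(2/delta)/n) = %g."), zeta, dev)
  }
  min(1, max(0, ub / (avg_loss + zeta)))
}

#' Minimum sample size for a relative expected-loss guarantee
#'
#' Smallest `N` ensuring that, with confidence `1 - delta`, the expected
#' absolute loss on new data exceeds the sample average by at most a
#' fraction `tau` of \eqn{\bar B R}:
#' \deqn{N \ge \left[\frac{2(1 + \sqrt{2\log(2/\delta)})}{\tau}\right]^2.}
#'
#' @inheritParams generalization_bound
#' @param tau Relative accuracy threshold (> 0).
#' @return Integer sample size (ceiling of the bound).
#' @export
min_n_expected <- function(delta, tau) {
  check_number(delta, "delta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(tau, "tau", lower = 0, strict_lower = TRUE)
  ceiling((2 * (1 + sqrt(2 * log(2 / delta))) / tau)^2)
}

#' Minimum sample size for a tail-probability guarantee
#'
#' Smallest `N` ensuring that, with confidence `1 - delta`, the probability
#' that a new sample's loss exceeds the training average by more than
#' \eqn{\gamma \bar B R} is at most `tau`:
#' \deqn{N \ge \left[\frac{2(1 + \sqrt{2\log(2/\delta)})}
#'   {\tau\gamma + \tau - 1}\right]^2,}
#' provided \eqn{\tau\gamma + \tau - 1 > 0}.
#'
#' @inheritParams generalization_bound
#' @param tau Probability threshold in (0, 1).
#' @param gamma Exceedance level (>= 0) in units of \eqn{\bar B R}.
#' @return Integer sample size (ceiling of the bound).
#' @export
min_n_tail <- function(delta, tau, gamma) {
  check_number(delta, "delta", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(tau, "tau", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(gamma, "gamma", lower = 0)
  denom <- tau * gamma + tau - 1
  if (denom <= 0) {
    stop_wdrolad("Requires tau*gamma + tau - 1 > 0 (got %g).", denom)
  }
  ceiling((2 * (1 + sqrt(2 * log(2 / delta))) / denom)^2)
}

#' Plug-in estimates of the bound constants
#'
#' Estimates `R` by the maximal observed joint-data norm
#' \eqn{\max_i \|(x_i, y_i)\|} and \eqn{\bar B} by the dual norm
#' \eqn{\|(-\hat\beta, 1)\|_*} of a fitted coefficient vector. These are
#' plug-ins, not almost-sure bounds: the guarantees assume `R` bounds the
#' data norm for all future draws and \eqn{\bar B} bounds the dual norm over
#' the whole feasible set.
#'
#' @param data Training data frame.
#' @param fit A `wdrolad_fit` (for \eqn{\bar B}).
#' @param norm Norm inducing the transport metric (for both constants).
#' @param response Name of the response column.
#' @return List with `r`, `b_bar`, and `avg_loss` (training mean absolute
#'   residual of `fit`).
#' @export
estimate_bound_inputs <- function(data, fit, norm = "l2", response = "y") {
  xy <- as_xy(data, response)
  norm <- as_norm_spec(norm)
  Z <- cbind(xy$X, xy$y)
  zero <- rep(0, ncol(Z))
  r <- max(apply(Z, 1, function(z) transport_cost(norm, z, zero)))
  list(r = r,
       b_bar = dual_norm(norm, fit$beta),
       avg_loss = mean(abs(xy$y - fit$intercept - drop(xy$X %*% fit$beta))))
}
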