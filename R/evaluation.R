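#' Score an estimate against the generating truth
#'
#' Computes the estimation-accuracy metrics of the benchmark, with
#' \eqn{\Delta = \hat\beta - \beta^*}:
#' \itemize{
#'   \item MSE: \eqn{\sum_i (y_i - \hat\beta_0 - x_i'\hat\beta)^2 / M} on the
#'     clean test rows (omitted when no test set is given);
#'   \item RR (relative risk): \eqn{\Delta'\Sigma\Delta / \beta^{*\prime}\Sigma\beta^*}
#'     — perfect score 0, null score 1;
#'   \item RTE (relative test error): \eqn{(\Delta'\Sigma\Delta + \sigma^2)/\sigma^2}
#'     — perfect score 1, null score SNR + 1;
#'   \item PVE (proportion of variance explained):
#'     \eqn{1 - (\Delta'\Sigma\Delta + \sigma^2)/(\beta^{*\prime}\Sigma\beta^* + \sigma^2)}
#'     — perfect score SNR/(SNR+1), null score 0.
#' }
#' The identity `rte = rr * snr + 1` holds exactly.
#'
#' @param beta_hat Estimated coefficients, or a `wdrolad_fit` (in which case
#'   `intercept_hat` is taken from the fit).
#' @param truth A [ground_truth()].
#' @param test Optional data frame of clean test rows for the MSE.
#' @param intercept_hat Estimated intercept (default 0).
#' @param response Name of the response column in `test`.
#' @return One-row tibble with columns `mse` (possibly `NA`), `rr`, `rte`,
#'   `pve`.
#' @export
score_estimate <- function(beta_hat, truth, test = NULL, intercept_hat = 0,
                           response = "y") {
  if (inherits(beta_hat, "wdrolad_fit")) {
    intercept_hat <- beta_hat$intercept
    beta_hat <- beta_hat$beta
  }
  stopifnot(inherits(truth, "ground_truth"))
  beta_hat <- as.numeric(beta_hat)
  if (length(beta_hat) != length(truth$beta_star)) {
    stop_wdrolad("`beta_hat` has length %d, truth has %d coefficients.",
                 length(beta_hat), length(truth$beta_star))
  }
  signal <- drop(crossprod(truth$beta_star, truth$Sigma %*% truth$beta_star))
  if (signal <= 0) {
    stop_wdrolad("RR is undefined for a zero true coefficient vector.")
  }
  delta <- beta_hat - truth$beta_star
  dsd <- drop(crossprod(delta, truth$Sigma %*% delta))
  s2 <- truth$sigma^2
  mse <- NA_real_
  if (!is.null(test)) {
    xy <- as_xy(test, response)
    mse <- mean((xy$y - intercept_hat - drop(xy$X %*% beta_hat))^2)
  }
  tibble::tibble(
    mse = mse,
    rr = dsd / signal,
    rte = (dsd + s2) / s2,
    pve = 1 - (dsd + s2) / (signal + s2)
  )
}

#' Residual scale for outlier screening
#'
#' Sample standard deviation (denominator n - 1) of the residuals over the
#' entire training set; the screening threshold is a multiple of this scale.
#'
#' @param residuals Numeric vector (length >= 2).
#' @return Nonnegative scalar; 0 (with a warning) for constant residuals.
#' @export
residual_sigma <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 2L) stop_wdrolad("Need at least 2 residuals.")
  s <- sd(residuals)
  if (s == 0) {
    warn("Residuals are constant: residual_sigma = 0 makes flagging all-or-nothing.")
  }
  s
}

#' Flag outliers by residual magnitude
#'
#' A sample is flagged when `|residual| > threshold * sigma_hat`.
#'
#' @param residuals Numeric residual vector.
#' @param sigma_hat Residual scale (>= 0), typically [residual_sigma()].
#' @param threshold Nonnegative multiplier.
#' @return Logical vector.
#' @export
flag_outliers <- function(residuals, sigma_hat, threshold) {
  check_number(sigma_hat, "sigma_hat", lower = 0)
  check_number(threshold, "threshold", lower = 0)
  abs(as.numeric(residuals)) > threshold * sigma_hat
}

#' ROC curve and AUC for residual-based detection
#'
#' Sweeps the decision threshold over all distinct score values (equivalently
#' all `|residual|/sigma_hat` cutoffs) to build the ROC curve, and computes
#' the AUC by the rank statistic, counting ties as one half.
#'
#' @param labels Logical (or 0/1) vector; `TRUE` marks a true outlier. Both
#'   classes must be present.
#' @param scores Numeric scores; larger means more outlying.
#' @return A `detection_result`: list with `roc` (tibble `fpr`, `tpr`,
#'   starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  scores <- as.numeric(scores)
  if (length(labels) != length(scores) || anyNA(labels) || anyNA(scores)) {
    stop_wdrolad("`labels` and `scores` must be equal-length and complete.")
  }
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) {
    stop_wdrolad("ROC needs both classes present (got %d positives, %d negatives).",
                 npos, nneg)
  }
  # rank-statistic AUC, ties counted 1/2 via midranks
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels]) - npos * (npos + 1) / 2) / (npos * nneg)

  o <- order(scores, decreasing = TRUE)
  lab_o <- labels[o]; sc_o <- scores[o]
  tp <- cumsum(lab_o); fp <- cumsum(!lab_o)
  last <- !duplicated(sc_o, fromLast = TRUE)  # one ROC vertex per distinct cutoff
  roc <- tibble::tibble(fpr = c(0, fp[last] / nneg), tpr = c(0, tp[last] / npos))
  structure(list(roc = roc, auc = auc), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> auc=%.4f (%d ROC vertices)\n",
              x$auc, nrow(x$roc)))
  invisible(x)
}

#' Residual-based outlier detection for a fitted model
#'
#' Convenience wrapper tying the pieces together: residuals of `fit` on
#' `data`, their sample standard deviation, hard flags at a given threshold,
#' and (when true labels are available) the full ROC/AUC of the score
#' `|residual| / sigma_hat`.
#'
#' @param fit A `wdrolad_fit`.
#' @param data Data frame with predictors, response, and optionally an
#'   `is_outlier` label column.
#' @param threshold Flagging multiplier (default 3).
#' @param response Name of the response column.
#' @return A `detection_result` with fields `flags`, `sigma_hat`,
#'   `threshold`, `scores`, and — when labels exist — `roc`, `auc`.
#' @export
detect_outliers <- function(fit, data, threshold = 3, response = "y") {
  r <- residuals(fit, data, response = response)
  s <- residual_sigma(r)
  scores <- if (s > 0) abs(r) / s else abs(r)
  out <- list(flags = flag_outliers(r, s, threshold), sigma_hat = s,
              threshold = threshold, scores = scores, roc = NULL, auc = NA_real_)
  if ("is_outlier" %in% names(data) && any(data$is_outlier) && !all(data$is_outlier)) {
    ra <- roc_auc(data$is_outlier, scores)
    out$roc <- ra$roc; out$auc <- ra$auc
  }
  structure(out, class = "detection_result")
}
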