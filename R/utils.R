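#' @importFrom rlang %||% abort warn
#' @importFrom stats coef median predict quantile rnorm runif sd setNames
#' @importFrom utils head modifyList
NULL

# Internal: consistent error signalling
stop_wdrolad <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "wdrolad_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_wdrolad("`%s` must be a single finite number.", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_wdrolad("`%s` = %g is outside the admissible range %s%g, %g%s.",
                 name, x, if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower) {
    stop_wdrolad("`%s` must be an integer >= %d.", name, lower)
  }
  as.integer(x)
}

# Extract a predictor matrix and response vector from a data frame.
# Predictors are every numeric column except `response` and known
# bookkeeping columns (is_outlier).
as_xy <- function(data, response = "y") {
  if (is.matrix(data)) data <- as.data.frame(data)
  if (!is.data.frame(data)) stop_wdrolad("`data` must be a data frame.")
  if (!response %in% names(data)) {
    stop_wdrolad("Response column `%s` not found in `data`.", response)
  }
  drop_cols <- c(response, "is_outlier", ".split")
  xcols <- setdiff(names(data), drop_cols)
  X <- as.matrix(data[xcols])
  if (!is.numeric(X)) stop_wdrolad("Predictor columns must all be numeric.")
  y <- data[[response]]
  if (anyNA(X) || anyNA(y)) stop_wdrolad("`data` contains missing values.")
  list(X = X, y = as.numeric(y), xnames = xcols)
}

# Deterministic substream seed, kept well below .Machine$integer.max
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 7919 + k) %% 2147483629
  }
  as.integer(s %% 2147483647)
}

new_fit_result <- function(beta, intercept, objective, status = "optimal",
                           method = "wdro", solver_meta = list(), xnames = NULL) {
  beta <- as.numeric(beta)
  if (!is.null(xnames)) names(beta) <- xnames
  structure(
    list(beta = beta, intercept = as.numeric(intercept),
         objective = as.numeric(objective), status = status,
         method = method, solver_meta = solver_meta),
    class = "wdrolad_fit"
  )
}

#' @export
print.wdrolad_fit <- function(x, ...) {
  cat(sprintf("<wdrolad_fit> method=%s status=%s objective=%.6g\n",
              x$method, x$status, x$objective))
  cat(sprintf("  intercept: %.6g\n", x$intercept))
  cat("  beta:", paste(signif(head(x$beta, 8), 4), collapse = " "),
      if (length(x$beta) > 8) "..." else "", "\n")
  invisible(x)
}

#' Predict from a fitted robust regression model
#'
#' @param object A `wdrolad_fit` object.
#' @param newdata Data frame with the same predictor columns used for fitting
#'   (a response column, if present, is ignored).
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.wdrolad_fit <- function(object, newdata, ...) {
  nm <- names(object$beta)
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  X <- if (!is.null(nm) && all(nm %in% names(newdata))) {
    as.matrix(newdata[nm])
  } else {
    xy <- as_xy(newdata, response = if ("y" %in% names(newdata)) "y" else names(newdata)[1])
    xy$X
  }
  drop(X %*% object$beta) + object$intercept
}

#' Residuals of a fitted robust regression model
#'
#' @param object A `wdrolad_fit` object.
#' @param data Data frame containing predictors and the response.
#' @param response Name of the response column.
#' @param ... Unused.
#' @return Numeric vector of residuals `y - intercept - x'beta`.
#' @export
residuals.wdrolad_fit <- function(object, data, response = "y", ...) {
  xy <- as_xy(data, response)
  xy$y - drop(xy$X %*% object$beta) - object$intercept
}
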