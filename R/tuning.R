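#' Regularization grid anchored at the maximal predictor-response covariance
#'
#' Candidate penalty values are log-equally spaced from
#' `lo_frac * a` up to \eqn{a = \|X'y\|_\infty}, the smallest penalty that
#' zeroes a lasso fit. For absolute-deviation losses the elementwise square
#' root of that grid is used instead, since the absolute loss is the square
#' root of the squared loss on a single observation and the useful penalty
#' scale shrinks accordingly.
#'
#' @param X Predictor matrix (or data frame of predictors).
#' @param y Response vector.
#' @param n_points Number of grid points (default 50).
#' @param lo_frac Lower endpoint as a fraction of `a` (default 0.005).
#' @param apply_sqrt Return the square-root grid (for absolute-deviation
#'   methods)?
#' @return Increasing positive numeric vector of length `n_points`.
#' @export
build_grid <- function(X, y, n_points = 50, lo_frac = 0.005, apply_sqrt = TRUE) {
  X <- as.matrix(X)
  n_points <- check_count(n_points, "n_points")
  check_number(lo_frac, "lo_frac", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (nrow(X) == 0L || length(y) != nrow(X)) {
    stop_wdrolad("`X` and `y` must be nonempty with matching rows.")
  }
  a <- max(abs(crossprod(X, y)))
  if (a == 0) stop_wdrolad("Degenerate design: ||X'y||_inf = 0.")
  g <- exp(seq(log(lo_frac * a), log(a), length.out = n_points))
  if (apply_sqrt) sqrt(g) else g
}

#' Median absolute validation residual
#'
#' The model-selection criterion: the median of the absolute residuals,
#' which hedges against heavy noise or contamination in the validation
#' samples.
#'
#' @param residuals Numeric vector.
#' @return Nonnegative scalar.
#' @export
mad_score <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) == 0L) stop_wdrolad("`residuals` is empty.")
  if (anyNA(residuals)) stop_wdrolad("`residuals` contains missing values.")
  median(abs(residuals))
}

#' Validation-split tuning plan
#'
#' @param grid Strictly increasing vector of candidate penalty values
#'   (all positive; 0 is permitted as an explicit extra first candidate).
#' @param split_fraction Fraction of the training rows used for fitting;
#'   the remainder is the validation set.
#' @param split_seed Integer seed for the deterministic split.
#' @return A `tuning_plan` object.
#' @export
tuning_plan <- function(grid, split_fraction = 0.75, split_seed = 1) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop_wdrolad("`grid` is empty.")
  if (any(grid < 0) || any(diff(grid) <= 0)) {
    stop_wdrolad("`grid` must be nonnegative and strictly increasing.")
  }
  check_number(split_fraction, "split_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(grid = grid, split_fraction = split_fraction,
                 split_seed = check_count(split_seed, "split_seed", 0L),
                 criterion = "mad"),
            class = "tuning_plan")
}

#' Select a penalty by minimum median absolute validation residual
#'
#' The training rows are split deterministically (seeded) into a fit set
#' and a validation set; each grid value is fit on the fit set and scored by
#' [mad_score()] of its validation residuals; the minimizer (ties broken
#' toward the smallest value) is refit on all training rows.
#'
#' @param data Data frame of training rows (predictors + response).
#' @param fitter Function `(data, param)` returning a `wdrolad_fit` (or any
#'   object with a `predict` method).
#' @param plan A [tuning_plan()].
#' @param response Name of the response column.
#' @return List with `best_param`, `fit` (refit on all rows), and `scores`
#'   (tibble of grid values and validation scores).
#' @export
tune_fit <- function(data, fitter, plan, response = "y") {
  stopifnot(inherits(plan, "tuning_plan"))
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  n_fit <- max(1L, min(n - 1L, floor(plan$split_fraction * n)))
  if (n < 2L) stop_wdrolad("Need at least 2 rows to split for validation.")
  set.seed(plan$split_seed)
  idx_fit <- sort(sample.int(n, n_fit))
  d_fit <- data[idx_fit, , drop = FALSE]
  d_val <- data[-idx_fit, , drop = FALSE]
  yval <- d_val[[response]]

  scores <- vapply(plan$grid, function(par) {
    f <- fitter(d_fit, par)
    mad_score(yval - predict(f, d_val))
  }, numeric(1))
  best <- plan$grid[which.min(scores)]  # which.min takes the first minimum
  list(best_param = best,
       fit = fitter(data, best),
       scores = tibble::tibble(param = plan$grid, mad = scores))
}

#' Wasserstein radius from the sample-size proportionality rule
#'
#' For large samples the appropriate ambiguity radius scales as
#' \eqn{\epsilon \propto N^{-1/m}} with `m` the joint dimension of
#' \eqn{(x, y)}; this utility applies that rule for a user-supplied
#' proportionality factor. Validation-based tuning remains the default for
#' small samples.
#'
#' @param n Sample size.
#' @param m Joint dimension (number of predictors + 1).
#' @param factor Proportionality constant.
#' @return Scalar radius `factor * n^(-1/m)`.
#' @export
epsilon_from_rate <- function(n, m, factor = 1) {
  n <- check_count(n, "n"); m <- check_count(m, "m")
  check_number(factor, "factor", lower = 0, strict_lower = TRUE)
  factor * n^(-1 / m)
}
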