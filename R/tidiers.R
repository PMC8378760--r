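#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted robust regression model
#'
#' @param x A `wdrolad_fit`.
#' @param ... Unused.
#' @return Tibble with one row per term (`term`, `estimate`), the intercept
#'   first when present.
#' @export
tidy.wdrolad_fit <- function(x, ...) {
  terms <- names(x$beta) %||% paste0("x", seq_along(x$beta))
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", estimate = x$intercept),
    tibble::tibble(term = terms, estimate = unname(x$beta)))
}

#' One-row summary of a fitted robust regression model
#'
#' @param x A `wdrolad_fit`.
#' @param ... Unused.
#' @return Tibble with `method`, `objective`, `status`, `n_nonzero`,
#'   `l1_norm`, and the penalty parameter used (`NA` for unpenalized fits).
#' @export
glance.wdrolad_fit <- function(x, ...) {
  par <- x$solver_meta$epsilon %||% x$solver_meta$lambda %||% NA_real_
  tibble::tibble(
    method = x$method,
    objective = x$objective,
    status = x$status,
    n_nonzero = sum(abs(x$beta) > 1e-8),
    l1_norm = sum(abs(x$beta)),
    penalty = par
  )
}

#' Plot the Wasserstein distance gap curve
#'
#' @param object A [wdist_gap_curve()] result.
#' @param ... Unused.
#' @return A ggplot: mean distances from the empirical distribution to the
#'   true and outlying components versus the contamination rate.
#' @export
autoplot.wdist_gap_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("w_true", "w_out"),
                              names_to = "target", values_to = "w1")
  long$target <- factor(long$target, c("w_true", "w_out"),
                        c("to true P", "to outlying P"))
  ggplot2::ggplot(long, ggplot2::aes(.data$q, .data$w1, colour = .data$target)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "contamination rate q",
                  y = expression(W[1] ~ "from empirical distribution"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `detection_result`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
autoplot.detection_result <- function(object, ...) {
  if (is.null(object$roc)) stop_wdrolad("No ROC curve available.")
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot experiment results across a sweep
#'
#' @param object An `experiment_result` from [run_scenario()].
#' @param metric Which metric to display (default `"mse"`).
#' @param ... Unused.
#' @return A ggplot of the mean metric per method against the swept value
#'   (or a per-method summary when nothing was swept).
#' @export
autoplot.experiment_result <- function(object, metric = "mse", ...) {
  sm <- object$summary
  if ("sweep_value" %in% names(sm) && !all(is.na(sm$sweep_value))) {
    ggplot2::ggplot(sm, ggplot2::aes(.data$sweep_value, .data[[metric]],
                                     colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = object$sweep %||% "sweep value", y = metric) +
      ggplot2::theme_minimal()
  } else {
    yvar <- intersect(c(metric, "median_auc"), names(sm))[1]
    ggplot2::ggplot(sm, ggplot2::aes(.data$method, .data[[yvar]])) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = yvar) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
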