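method_registry <- function() {
  tibble::tribble(
    ~method,     ~tuned, ~ad_loss, ~detection,
    "wdro_l2",   TRUE,   TRUE,     TRUE,
    "wdro_linf", TRUE,   TRUE,     FALSE,
    "lad_l1",    TRUE,   TRUE,     TRUE,
    "lad_l2",    TRUE,   TRUE,     FALSE,
    "ols",       FALSE,  FALSE,    FALSE,
    "ridge",     TRUE,   FALSE,    FALSE,
    "lasso",     TRUE,   FALSE,    FALSE,
    "en",        TRUE,   FALSE,    FALSE,
    "m_huber",   FALSE,  FALSE,    TRUE,
    "m_talwar",  FALSE,  FALSE,    TRUE,
    "m_fair",    FALSE,  FALSE,    TRUE
  )
}

check_methods <- function(methods, detection_only = FALSE) {
  reg <- method_registry()
  bad <- setdiff(methods, reg$method)
  if (length(bad)) {
    stop_wdrolad("Unknown method id(s): %s. Available: %s.",
                 paste(bad, collapse = ", "), paste(reg$method, collapse = ", "))
  }
  if (detection_only) {
    nd <- setdiff(methods, reg$method[reg$detection])
    if (length(nd)) {
      stop_wdrolad("Method(s) not in the detection-capable set: %s.",
                   paste(nd, collapse = ", "))
    }
  }
  reg[match(methods, reg$method), ]
}

method_fitter <- function(method) {
  switch(method,
    wdro_l2 = function(d, par) fit_wdro(d, epsilon = par, norm = "l2"),
    wdro_linf = function(d, par) fit_wdro(d, epsilon = par, norm = "linf"),
    lad_l1 = function(d, par) fit_regularized_lad(d, "l1", lambda = par),
    lad_l2 = function(d, par) fit_regularized_lad(d, "l2", lambda = par),
    ols = function(d, par) fit_sr_baseline(d, "ols"),
    ridge = function(d, par) fit_sr_baseline(d, "ridge", lambda = par),
    lasso = function(d, par) fit_sr_baseline(d, "lasso", lambda = par),
    en = function(d, par) fit_sr_baseline(d, "en", lambda = par, alpha = 0.5),
    m_huber = function(d, par) fit_mestimator(d, "huber"),
    m_talwar = function(d, par) fit_mestimator(d, "talwar"),
    m_fair = function(d, par) fit_mestimator(d, "fair")
  )
}

fit_one_method <- function(method, info, train, seed, grid_points) {
  fitter <- method_fitter(method)
  if (!info$tuned) {
    return(list(fit = fitter(train, 0), selected = NA_real_))
  }
  xy <- as_xy(train, "y")
  grid <- build_grid(xy$X, xy$y, n_points = grid_points,
                     apply_sqrt = info$ad_loss)
  plan <- tuning_plan(grid, split_seed = seed)
  tn <- tune_fit(train, fitter, plan)
  list(fit = tn$fit, selected = tn$best_param)
}

#' Run a synthetic benchmark scenario
#'
#' Replicates the benchmark protocol: for each sweep value and replicate, a
#' contaminated training set and a clean test set are generated, every
#' method is tuned on a validation split of the training data (minimum
#' median absolute validation residual over the standard 50-point grid),
#' refit on all training rows, and scored against the generating truth on
#' the clean test set. Results are averaged over replicates.
#'
#' When the signal-to-noise ratio is swept, the predictor correlation of
#' each dataset is drawn as \eqn{0.8 \times U(0.2, 0.4)}; when the
#' correlation is swept, the SNR is held at the scenario's value (0.5 by
#' default).
#'
#' @param spec A [scenario_spec()].
#' @param methods Character vector of method ids among `wdro_l2`,
#'   `wdro_linf`, `lad_l1`, `lad_l2`, `ols`, `ridge`, `lasso`, `en`,
#'   `m_huber`, `m_talwar`, `m_fair`.
#' @param reps Replicates (independent datasets) per sweep value.
#' @param sweep `"none"`, `"snr"` or `"rho"`.
#' @param sweep_values Values for the swept quantity. Defaults: ten points
#'   log-spaced on \code{[0.05, 2]} for SNR; 0.1, ..., 0.9 for rho.
#' @param seed Integer master seed; every replicate derives its own stream.
#' @param grid_points Tuning-grid size (default 50).
#' @return An `experiment_result`: list with `results` (one row per method,
#'   sweep value and replicate), `summary` (means over replicates), `spec`.
#' @export
run_scenario <- function(spec, methods, reps = 10,
                         sweep = c("none", "snr", "rho"), sweep_values = NULL,
                         seed = 1, grid_points = 50) {
  stopifnot(inherits(spec, "scenario_spec"))
  sweep <- match.arg(sweep)
  info <- check_methods(methods)
  reps <- check_count(reps, "reps")
  if (sweep == "snr" && is.null(sweep_values)) {
    sweep_values <- exp(seq(log(0.05), log(2), length.out = 10))
  }
  if (sweep == "rho" && is.null(sweep_values)) {
    sweep_values <- seq(0.1, 0.9, by = 0.1)
  }
  if (sweep == "none") sweep_values <- NA_real_

  rows <- list()
  for (iv in seq_along(sweep_values)) {
    for (rep in seq_len(reps)) {
      dseed <- derive_seed(seed, iv, rep)
      sp <- spec
      if (sweep == "snr") {
        sp$snr <- sweep_values[iv]; sp$sigma <- NULL
        set.seed(derive_seed(dseed, 99))
        sp$rho <- 0.8 * runif(1, 0.2, 0.4)
      } else if (sweep == "rho") {
        sp$rho <- sweep_values[iv]
        if (is.null(sp$snr)) { sp$snr <- 0.5; sp$sigma <- NULL }
      }
      sp$seed <- dseed
      ds <- generate_dataset(sp)
      train <- dplyr::select(ds$data, -dplyr::any_of("is_outlier"))
      for (im in seq_along(methods)) {
        res <- fit_one_method(methods[im], info[im, ], train,
                              derive_seed(dseed, im), grid_points)
        sc <- score_estimate(res$fit, ds$truth, ds$test)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = methods[im], sweep_value = sweep_values[iv],
          replicate = rep, seed = dseed, selected_param = res$selected,
          mse = sc$mse, rr = sc$rr, rte = sc$rte, pve = sc$pve)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(method, sweep_value) |>
    dplyr::summarise(dplyr::across(c(mse, rr, rte, pve), mean), .groups = "drop")
  structure(list(results = results, summary = summary, spec = spec,
                 sweep = sweep, methods = methods, seed = seed),
            class = "experiment_result")
}

#' Run the outlier-cloud detection experiment
#'
#' For each replicate a training cloud dataset and an independent evaluation
#' cloud dataset are generated. Penalized methods are tuned on a validation
#' split of the training set by minimum median absolute residual and refit;
#' each fitted model's residuals on the evaluation set, scaled by their
#' sample standard deviation, score the evaluation samples, and ROC/AUC are
#' computed against the true outlier labels. For the Wasserstein l2 DRO and
#' the l1-regularized LAD the full AUC-versus-penalty sweep over the tuning
#' grid is also recorded (the flatness of the DRO curve is one of the
#' method's selling points).
#'
#' @param n Training (and evaluation) sample size.
#' @param sigma Clean-noise standard deviation.
#' @param q Outlier probability.
#' @param delta_r Outlier response offset.
#' @param methods Detection-capable method ids among `wdro_l2`, `lad_l1`,
#'   `m_huber`, `m_talwar`, `m_fair`.
#' @param reps Number of replicates.
#' @param seed Integer master seed.
#' @param grid_points Tuning-grid size.
#' @return An `experiment_result` with `results` (per method and replicate:
#'   selected penalty and AUC; AUC is `NA` when the evaluation set has a
#'   single class, e.g. `q = 0`), `sweep` (per-grid-value AUC for the
#'   penalized methods) and `summary` (median and mean AUC per method).
#' @export
run_outlier_experiment <- function(n = 60, sigma = 0.5, q = 0.3,
                                   delta_r = 5 * sigma,
                                   methods = c("wdro_l2", "lad_l1", "m_huber",
                                               "m_talwar", "m_fair"),
                                   reps = 20, seed = 1, grid_points = 50) {
  info <- check_methods(methods, detection_only = TRUE)
  reps <- check_count(reps, "reps")
  sweep_methods <- intersect(methods, c("wdro_l2", "lad_l1"))

  rows <- list(); sweeps <- list()
  for (rep in seq_len(reps)) {
    tr <- generate_cloud_dataset(n, q, sigma, delta_r,
                                 seed = derive_seed(seed, rep, 1))
    ev <- generate_cloud_dataset(n, q, sigma, delta_r,
                                 seed = derive_seed(seed, rep, 2))
    train <- dplyr::select(tr$data, -dplyr::any_of("is_outlier"))
    eval_auc <- function(fit) {
      det <- detect_outliers(fit, ev$data)
      det$auc
    }
    xy <- as_xy(train, "y")
    grid <- build_grid(xy$X, xy$y, n_points = grid_points, apply_sqrt = TRUE)
    for (im in seq_along(methods)) {
      m <- methods[im]
      res <- fit_one_method(m, info[im, ], train, derive_seed(seed, rep, 3, im),
                            grid_points)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, replicate = rep, seed = tr$spec$seed,
        selected_param = res$selected, auc = eval_auc(res$fit))
      if (m %in% sweep_methods) {
        fitter <- method_fitter(m)
        aucs <- vapply(grid, function(par) eval_auc(fitter(train, par)),
                       numeric(1))
        sweeps[[length(sweeps) + 1L]] <- tibble::tibble(
          method = m, replicate = rep, grid_index = seq_along(grid),
          param = grid, auc = aucs)
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(method) |>
    dplyr::summarise(median_auc = median(auc), mean_auc = mean(auc),
                     .groups = "drop")
  structure(list(results = results, sweep = dplyr::bind_rows(sweeps),
                 summary = summary, seed = seed,
                 config = list(n = n, sigma = sigma, q = q, delta_r = delta_r,
                               grid_points = grid_points)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$summary)
  invisible(x)
}
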