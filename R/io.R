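#' Write a regression dataset to CSV (with a JSON truth sidecar)
#'
#' The CSV carries the predictor columns `x1..xK`, the response `y`, and the
#' outlier labels `is_outlier` when present; numbers are written with 17
#' significant digits so the round trip is lossless. When the dataset
#' carries its generating truth, a sidecar `<path minus extension>.json`
#' records `beta_star`, `intercept_star`, `sigma`, `rho`, `family`, `seed`.
#'
#' @param data A `regression_data` object or a plain data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  df <- if (inherits(data, "regression_data")) data$data else tibble::as_tibble(data)
  cols <- vapply(df, function(col) {
    if (is.logical(col)) as.character(as.integer(col))
    else sprintf("%.17g", col)
  }, character(nrow(df)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(cols, 1, paste, collapse = ","))
  writeLines(lines, path)
  if (inherits(data, "regression_data") && !is.null(data$truth)) {
    sidecar <- paste0(sub("\\.[A-Za-z]+$", "", path), ".json")
    jsonlite::write_json(
      list(beta_star = data$truth$beta_star,
           intercept_star = data$truth$intercept_star,
           sigma = data$truth$sigma,
           rho = data$spec$rho %||% NA,
           family = data$spec$family,
           seed = data$spec$seed),
      sidecar, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Read a regression dataset from CSV
#'
#' Validates the layout (a numeric response column, numeric predictors, an
#' optional 0/1 `is_outlier` column) with errors naming the offending
#' column, and re-attaches the generating truth from the JSON sidecar when
#' one exists next to the file.
#'
#' @param path CSV path written by [write_dataset()] (or any conforming CSV).
#' @param response Name of the response column (default `"y"`).
#' @return A tibble; if a sidecar is found, the truth is attached as the
#'   `"truth"` attribute (a [ground_truth()] with compound-symmetric
#'   covariance rebuilt from `rho` where available).
#' @export
read_dataset <- function(path, response = "y") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!response %in% names(df)) {
    stop_wdrolad("Column `%s` (response) is missing from %s.", response, path)
  }
  for (nm in setdiff(names(df), "is_outlier")) {
    if (!is.numeric(df[[nm]])) {
      stop_wdrolad("Column `%s` contains non-numeric cells.", nm)
    }
    if (anyNA(df[[nm]])) {
      stop_wdrolad("Column `%s` contains missing values (first at row %d).",
                   nm, which(is.na(df[[nm]]))[1])
    }
  }
  if ("is_outlier" %in% names(df)) {
    v <- df$is_outlier
    if (!all(v %in% c(0, 1, TRUE, FALSE))) {
      stop_wdrolad("Column `is_outlier` must be 0/1.")
    }
    df$is_outlier <- as.logical(v)
  }
  out <- tibble::as_tibble(df)
  sidecar <- paste0(sub("\\.[A-Za-z]+$", "", path), ".json")
  if (file.exists(sidecar)) {
    tr <- jsonlite::fromJSON(sidecar)
    p <- length(tr$beta_star)
    Sigma <- if (!is.null(tr$rho) && !is.na(tr$rho) &&
                 !identical(tr$family, "cloud")) {
      build_sigma(p, tr$rho)
    } else if (identical(tr$family, "cloud")) diag(16, p) else diag(p)
    attr(out, "truth") <- ground_truth(tr$beta_star, tr$intercept_star,
                                       tr$sigma, Sigma)
  }
  out
}

#' Read scenario configurations from JSON
#'
#' Accepts a single scenario object or an array of them; each is validated
#' through [scenario_spec()] (so e.g. a contamination rate of 0.5 or more
#' triggers the minority-assumption warning).
#'
#' @param path JSON path.
#' @return A list of `scenario_spec` objects.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(cfg$family)) cfg <- list(cfg)
  lapply(cfg, function(x) {
    known <- c("family", "q", "snr", "sigma", "rho", "n_train", "n_test", "seed")
    bad <- setdiff(names(x), known)
    if (length(bad)) {
      stop_wdrolad("Unknown configuration field(s): %s.", paste(bad, collapse = ", "))
    }
    do.call(scenario_spec, x)
  })
}

#' Write an experiment result (or any tidy object) to JSON
#'
#' @param result An `experiment_result`, `detection_result`, tibble or list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  x <- if (inherits(result, "experiment_result")) {
    unclass(result)
  } else if (inherits(result, "detection_result")) {
    unclass(result)
  } else result
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", force = TRUE)
  invisible(path)
}

#' Export ROC points as CSV
#'
#' @param detection A `detection_result` with an ROC curve.
#' @param path Output CSV path (columns `fpr,tpr`).
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(detection, path) {
  stopifnot(inherits(detection, "detection_result"))
  if (is.null(detection$roc)) stop_wdrolad("No ROC curve available (single class?).")
  utils::write.csv(detection$roc, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a tuning plan
#'
#' @param plan A [tuning_plan()].
#' @return `plan_to_json`: a JSON string; `plan_from_json`: a `tuning_plan`.
#' @export
plan_to_json <- function(plan) {
  stopifnot(inherits(plan, "tuning_plan"))
  as.character(jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, digits = NA))
}

#' @rdname plan_to_json
#' @param json JSON string produced by `plan_to_json()`.
#' @export
plan_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  tuning_plan(x$grid, x$split_fraction, x$split_seed)
}
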