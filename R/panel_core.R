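#' @keywords internal
"_PACKAGE"

# Canonical logical column names of a long-format pollutant panel.
.panel_id_cols <- c("city_id", "city_name", "x", "y", "week")
.default_predictors <- c("so2", "no2", "pm10", "co", "o3")
.default_response <- "pm25"
.default_units <- c(
  so2 = "ug/m3", no2 = "ug/m3", pm10 = "ug/m3", co = "mg/m3",
  o3 = "ug/m3", pm25 = "ug/m3"
)

#' Construct a space-time panel dataset
#'
#' A `panel_dataset` is the container shared by every modelling stage: one
#' record per (city, week) holding planar coordinates `(x, y)`, an integer
#' week index, the predictor columns and the response column. Records are
#' stored sorted by `(city_id, week)`.
#'
#' @param data data.frame with columns `city_id`, `city_name`, `x`, `y`,
#'   `week`, plus one numeric column per predictor and one for the response.
#' @param predictors character vector of predictor column names.
#' @param response name of the response column.
#' @param units named character vector mapping variable names to unit strings.
#' @return An object of class `panel_dataset`: a list with elements `data`
#'   (the sorted records), `predictors`, `response`, `units` and `locations`
#'   (one row per distinct city: id, name, x, y).
#' @export
panel_dataset <- function(data,
                          predictors = .default_predictors,
                          response = .default_response,
                          units = .default_units) {
  stopifnot(is.data.frame(data))
  needed <- c(.panel_id_cols, predictors, response)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(needed, "city_name")
  for (cn in num_cols) {
    if (!is.numeric(data[[cn]])) {
      stop("panel column '", cn, "' must be numeric", call. = FALSE)
    }
  }
  if (any(data$week != as.integer(data$week), na.rm = TRUE)) {
    stop("week index must be integer-valued", call. = FALSE)
  }
  data <- data[order(data$city_id, data$week), needed, drop = FALSE]
  rownames(data) <- NULL

  dup <- duplicated(data[, c("city_id", "week")])
  if (any(dup)) {
    offenders <- unique(data[dup, c("city_id", "week")])
    stop("duplicated (city_id, week) pair(s): ",
         paste(sprintf("(%s, %s)", offenders$city_id, offenders$week),
               collapse = " "),
         call. = FALSE)
  }

  locations <- unique(data[, c("city_id", "city_name", "x", "y")])
  rownames(locations) <- NULL
  if (anyDuplicated(locations$city_id)) {
    stop("a city_id maps to more than one (name, x, y) triple", call. = FALSE)
  }
  if (!all(is.finite(locations$x)) || !all(is.finite(locations$y))) {
    stop("city coordinates must be finite", call. = FALSE)
  }

  structure(
    list(data = data, predictors = predictors, response = response,
         units = units, locations = locations),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf(
    "panel_dataset: %d records, %d cities x %d weeks\n",
    nrow(x$data), nrow(x$locations), length(unique(x$data$week))
  ))
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("  response:  ", x$response, "\n")
  invisible(x)
}

#' Number of records in a panel
#' @param ds a `panel_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(ds) nrow(ds$data)

#' Design matrix of a panel
#'
#' Returns the n x p fixed-effects design `[1, X1..X5]` (intercept first,
#' predictors in panel order).
#'
#' @param ds a `panel_dataset`.
#' @return Numeric matrix with `length(ds$predictors) + 1` columns.
#' @export
design_matrix <- function(ds) {
  X <- cbind(1, as.matrix(ds$data[, ds$predictors, drop = FALSE]))
  colnames(X) <- c("intercept", ds$predictors)
  X
}

#' Load a panel from a long-format CSV file
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector mapping logical column names
#'   (`city_id`, `city_name`, `x`, `y`, `week`, predictors, response) to the
#'   file's column names; defaults to the identity mapping.
#' @param predictors,response,units passed to [panel_dataset()].
#' @return A validated `panel_dataset`, records sorted by `(city_id, week)`.
#' @export
load_panel <- function(path, schema = NULL,
                       predictors = .default_predictors,
                       response = .default_response,
                       units = .default_units) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  logical_cols <- c(.panel_id_cols, predictors, response)
  if (is.null(schema)) {
    schema <- stats::setNames(logical_cols, logical_cols)
  }
  missing_map <- setdiff(logical_cols, names(schema))
  if (length(missing_map) > 0L) {
    stop("schema does not name column(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  absent <- schema[logical_cols][!(schema[logical_cols] %in% names(raw))]
  if (length(absent) > 0L) {
    stop("input file lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  data <- raw[, schema[logical_cols], drop = FALSE]
  names(data) <- logical_cols
  for (cn in setdiff(logical_cols, "city_name")) {
    if (!is.numeric(data[[cn]])) {
      coerced <- suppressWarnings(as.numeric(data[[cn]]))
      bad <- which(is.na(coerced) & !is.na(data[[cn]]))
      if (length(bad) > 0L) {
        stop("non-numeric value in column '", cn, "' at data row ",
             bad[1L], call. = FALSE)
      }
      data[[cn]] <- coerced
    }
  }
  panel_dataset(data, predictors = predictors, response = response,
                units = units)
}

#' Write a panel to CSV
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(ds, path))` restores the
#' dataset (floats round-trip at 15 significant digits).
#'
#' @param ds a `panel_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(ds, path) {
  df <- ds$data
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate and clean a panel
#'
#' Asserts the container invariants and drops any record holding a missing
#' value in a coordinate, the week index, a predictor or the response.
#' Idempotent: validating a validated panel changes nothing.
#'
#' @param ds a `panel_dataset`.
#' @return The cleaned `panel_dataset` with an added attribute
#'   `dropped` holding the number of removed records.
#' @export
validate_panel <- function(ds) {
  stopifnot(inherits(ds, "panel_dataset"))
  needed <- c(.panel_id_cols, ds$predictors, ds$response)
  num_cols <- setdiff(needed, "city_name")
  keep <- rowSums(is.na(ds$data[, num_cols, drop = FALSE])) == 0L
  dropped <- sum(!keep)
  data <- ds$data[keep, , drop = FALSE]
  p <- length(ds$predictors) + 1L
  if (nrow(data) < p + 2L) {
    stop("insufficient data: ", nrow(data), " complete records, need at least ",
         p + 2L, call. = FALSE)
  }
  out <- panel_dataset(data, ds$predictors, ds$response, ds$units)
  attr(out, "dropped") <- dropped
  out
}

# PM2.5 annual-mean AQI grade breakpoints (ug/m3); grade VI is unbounded.
.aqi_breaks <- c(0, 35, 75, 115, 150, 250, Inf)
.aqi_grades <- c("I", "II", "III", "IV", "V", "VI")

#' Grade an annual PM2.5 concentration
#'
#' Maps an annual-mean PM2.5 concentration to the six-level air-quality grade
#' with breakpoints 35/75/115/150/250 ug/m3. A boundary value belongs to the
#' lower grade (grade I is "<= 35").
#'
#' @param pm25_annual positive annual-mean PM2.5 concentration(s), ug/m3.
#' @return A data.frame of class `aqi_grade` with columns `value`, `grade`
#'   (ordered factor I..VI), `lower`, `upper` (upper bound of grade VI is
#'   `Inf`).
#' @export
aqi_grade <- function(pm25_annual) {
  if (!is.numeric(pm25_annual) || any(!is.finite(pm25_annual)) ||
      any(pm25_annual <= 0)) {
    stop("pm25_annual must be finite and > 0", call. = FALSE)
  }
  idx <- findInterval(pm25_annual, .aqi_breaks, left.open = TRUE,
                      rightmost.closed = FALSE)
  out <- data.frame(
    value = pm25_annual,
    grade = factor(.aqi_grades[idx], levels = .aqi_grades, ordered = TRUE),
    lower = .aqi_breaks[idx],
    upper = .aqi_breaks[idx + 1L]
  )
  class(out) <- c("aqi_grade", "data.frame")
  out
}

#' Write a fitted object or comparison table to disk
#'
#' Per-record local-model output goes to CSV (one row per record: local
#' coefficients, fitted value, residual); scalar summaries (global fits,
#' mixed-model fits, comparison tables) go to JSON.
#'
#' @param obj a `global_fit`, `lmm_fit`, `local_fit` or `comparison_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) UseMethod("write_results")

.check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  invisible(TRUE)
}

#' @export
write_results.local_fit <- function(obj, path) {
  .check_writable(path)
  if (is.null(obj$coef) || nrow(obj$coef) == 0L) {
    stop("local fit holds no records; refusing to write an empty file",
         call. = FALSE)
  }
  df <- as.data.frame(obj$coef)
  df$fitted <- obj$fitted
  df$residual <- obj$residuals
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.global_fit <- function(obj, path) {
  .check_writable(path)
  out <- list(
    model = "ols",
    coefficients = as.list(obj$beta),
    std_error = as.list(obj$se),
    t_value = as.list(obj$tvals),
    p_value = as.list(obj$pvals),
    standardized = as.list(obj$standardized),
    ra2 = obj$ra2, aicc = obj$aicc, rmse = obj$rmse, mae = obj$mae,
    n = obj$n, p = obj$p
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.lmm_fit <- function(obj, path) {
  .check_writable(path)
  out <- list(
    model = "lmm",
    fixed_effects = as.list(obj$beta_fixed),
    std_error = as.list(obj$se_fixed),
    variance_components = as.list(obj$var_components),
    ar1_r = obj$ar1_r, resid_var = obj$resid_var,
    rc2 = obj$rc2, aicc = obj$aicc,
    loglik_ml = obj$loglik_ml, loglik_reml = obj$loglik_reml,
    converged = obj$converged, n_iter = obj$n_iter
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.comparison_table <- function(obj, path) {
  .check_writable(path)
  rows <- split(as.data.frame(obj), seq_len(nrow(obj)))
  out <- stats::setNames(
    lapply(rows, function(r) as.list(r[setdiff(names(r), "model")])),
    obj$model
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
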