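#' Read a concentration/signal series from CSV
#'
#' Expects the canonical dialect: header `time_min,value,channel`, one row per
#' sample, decimal point, UTF-8.  The grid is validated (uniform spacing); a
#' gap is reported with the offending timestamps.
#'
#' @param path Path to the CSV file.
#' @param expected_channel Optional channel the file must carry
#'   (`"plasma"`, `"lung"`, `"ppb"`, `"volt"`); mismatch is an error.
#' @return A [conc_series()].
#' @export
read_series <- function(path, expected_channel = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("format error reading %s: %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  need <- c("time_min", "value", "channel")
  if (!all(need %in% names(df)) || nrow(df) == 0L) {
    stop(sprintf("format error: %s must have columns time_min,value,channel and at least one row",
                 path), call. = FALSE)
  }
  if (!is.numeric(df$time_min) || !is.numeric(df$value)) {
    stop(sprintf("format error: non-numeric time_min/value in %s", path), call. = FALSE)
  }
  ch <- unique(df$channel)
  if (length(ch) != 1L) {
    stop(sprintf("format error: mixed channels in %s", path), call. = FALSE)
  }
  if (!is.null(expected_channel) && ch != expected_channel) {
    stop(sprintf("channel mismatch: %s carries '%s', expected '%s'",
                 path, ch, expected_channel), call. = FALSE)
  }
  conc_series(df$time_min, df$value, ch)
}

#' Write a concentration/signal series to CSV
#'
#' Canonical CSV dialect (`time_min,value,channel`), values at 10 significant
#' digits; byte-deterministic for identical input.
#'
#' @param series A [conc_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "conc_series"))
  ch <- series_channel(series)
  lines <- c("time_min,value,channel",
             sprintf("%s,%s,%s",
                     formatC(series$time_min, digits = 10, format = "g"),
                     formatC(series$value, digits = 10, format = "g"),
                     ch))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value configuration for the TCI / study protocol.  Recognized
#' keys: `weight_kg`, `target_ugml`, `t_start_min`, `t_stop_min`,
#' `duration_min`, `max_rate_ugmin` (pump ceiling in µg/min, converted to the
#' package-internal mg/min), `model`, `cv`, `seed`.  Unknown keys are
#' rejected.
#'
#' @param path Path to the YAML file.
#' @return A named list of configuration values (rates converted to mg/min).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("weight_kg", "target_ugml", "t_start_min", "t_stop_min",
               "duration_min", "max_rate_ugmin", "model", "cv", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed)) {
    stop("config error: `seed` must be an integer", call. = FALSE)
  }
  if (!is.null(cfg$max_rate_ugmin)) cfg$max_rate_mgmin <- cfg$max_rate_ugmin / 1000
  cfg
}

#' Write and read a calibration as a key-value file
#'
#' @param calib A [quadratic_calibration()].
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the [quadratic_calibration()].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "quadratic_calibration"))
  yaml::write_yaml(list(a = calib$a, b = calib$b, channel = calib$channel), path)
  invisible(path)
}

#' @rdname write_calibration
#' @param path File path.
#' @export
read_calibration <- function(path) {
  v <- yaml::read_yaml(path)
  quadratic_calibration(v$a, v$b, v$channel)
}

#' Write a fit report as plain key-value text
#'
#' One `key: value` line per item (model, each parameter, R2, SSE, n,
#' convergence flags), parseable without any library.
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param path Output path for the report; residuals go to
#'   `paste0(path, "_residuals.csv")` when `residuals = TRUE`.
#' @param residuals Write the residual series CSV alongside?
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path, residuals = TRUE) {
  stopifnot(inherits(fit, "fit_result"))
  p <- unlist(fit$parameters)
  lines <- c(
    sprintf("model: %s", fit$model_kind),
    sprintf("%s: %.10g", names(p), p),
    sprintf("r2: %.10g", fit$r2),
    sprintf("sse: %.10g", fit$sse),
    sprintf("n: %d", fit$n),
    sprintf("converged: %s", fit$converged),
    sprintf("scale_degenerate: %s", fit$scale_degenerate)
  )
  writeLines(lines, path)
  if (residuals) {
    utils::write.csv(fit$residuals, paste0(path, "_residuals.csv"), row.names = FALSE)
  }
  invisible(path)
}
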