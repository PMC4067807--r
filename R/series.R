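#' Uniform-grid concentration / signal time series
#'
#' The universal exchange type between pipeline stages: a time series sampled
#' on a strictly increasing, uniformly spaced grid of minutes.  Depending on
#' `channel` the values are plasma or lung concentrations in micrograms per
#' millilitre, or raw breath signal in ppb or volt.
#'
#' @param time_min Numeric vector of sample times in minutes; strictly
#'   increasing with constant spacing, length at least 2.
#' @param value Numeric vector of the same length; all values finite.
#' @param channel One of `"plasma"`, `"lung"`, `"ppb"`, `"volt"`.
#' @return A data frame of class `conc_series` with columns `time_min` and
#'   `value` and a `channel` attribute.
#' @examples
#' s <- conc_series(1:5, c(0, 1, 2, 2, 2), "plasma")
#' series_dt(s)
#' @export
conc_series <- function(time_min, value, channel = c("plasma", "lung", "ppb", "volt")) {
  channel <- match.arg(channel)
  time_min <- as.numeric(time_min)
  value <- as.numeric(value)
  if (length(time_min) != length(value)) {
    stop("`time_min` and `value` must have the same length", call. = FALSE)
  }
  if (length(time_min) < 2L) {
    stop("a concentration series needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(time_min) || anyNA(value) || !all(is.finite(value))) {
    stop("series times and values must be finite and non-missing", call. = FALSE)
  }
  d <- diff(time_min)
  if (any(d <= 0)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  if (max(d) - min(d) > 1e-8 * max(d)) {
    bad <- time_min[which(abs(d - stats::median(d)) > 1e-8 * max(d)) + 1L]
    stop(sprintf("series grid is not uniform; offending timestamps: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(data.frame(time_min = time_min, value = value),
            channel = channel, class = c("conc_series", "data.frame"))
}

#' @rdname conc_series
#' @param x A `conc_series` object.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "conc_series"))
  x$time_min
}

#' @rdname conc_series
#' @export
series_values <- function(x) {
  stopifnot(inherits(x, "conc_series"))
  x$value
}

#' @rdname conc_series
#' @export
series_channel <- function(x) {
  stopifnot(inherits(x, "conc_series"))
  attr(x, "channel")
}

#' @rdname conc_series
#' @export
series_dt <- function(x) {
  stopifnot(inherits(x, "conc_series"))
  stats::median(diff(x$time_min))
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> channel=%s, n=%d, t=[%g, %g] min, dt=%g min\n",
              series_channel(x), nrow(x), x$time_min[1L],
              x$time_min[nrow(x)], series_dt(x)))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

# internal: assert two series share a grid
check_same_grid <- function(a, b) {
  ta <- series_times(a); tb <- series_times(b)
  if (length(ta) != length(tb) || max(abs(ta - tb)) > 1e-8) {
    stop("series are not on the same time grid", call. = FALSE)
  }
  invisible(TRUE)
}
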