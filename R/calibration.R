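#' Zero-intercept quadratic calibration
#'
#' Second-order polynomial map `y = a x^2 + b x` between a measured breath
#' signal `x` (ppb or volt) and a modelled lung concentration `y` (µg/ml).
#' The intercept is identically zero: no drug in breath means no drug in the
#' lung compartment.  With `a < 0` the map is concave and invertible only up
#' to the vertex value `b^2 / (4 |a|)`.
#'
#' @param a Quadratic coefficient, (µg/ml)/signal^2.
#' @param b Linear coefficient, (µg/ml)/signal; must be positive for a usable
#'   ascending branch.
#' @param channel Signal channel the calibration refers to: `"ppb"` or `"volt"`.
#' @return An object of class `quadratic_calibration`.
#' @examples
#' quadratic_calibration(-5.9, 9.23, "ppb")
#' @export
quadratic_calibration <- function(a, b, channel = c("ppb", "volt")) {
  channel <- match.arg(channel)
  if (!(is.numeric(a) && length(a) == 1L && is.finite(a)) ||
      !(is.numeric(b) && length(b) == 1L && is.finite(b))) {
    stop("calibration coefficients must be single finite numbers", call. = FALSE)
  }
  if (b <= 0) stop("calibration needs b > 0 for an ascending branch", call. = FALSE)
  structure(list(a = a, b = b, channel = channel), class = "quadratic_calibration")
}

#' @export
print.quadratic_calibration <- function(x, ...) {
  cat(sprintf("y = %g*x^2 + %g*x + 0   [x: %s signal, y: ug/ml]\n", x$a, x$b, x$channel))
  if (x$a < 0) cat(sprintf("  invertible for y <= %g ug/ml (vertex)\n", calibration_vertex(x)))
  invisible(x)
}

#' @rdname quadratic_calibration
#' @param calib A `quadratic_calibration`.
#' @return `calibration_vertex()`: the maximum attainable `y` on the ascending
#'   branch (`b^2 / (4 |a|)` for `a < 0`, `Inf` otherwise).
#' @export
calibration_vertex <- function(calib) {
  stopifnot(inherits(calib, "quadratic_calibration"))
  if (calib$a < 0) calib$b^2 / (4 * abs(calib$a)) else Inf
}

#' Apply a calibration to breath signal
#'
#' @param calib A [quadratic_calibration()].
#' @param x Breath signal values (non-negative).
#' @return Lung concentration `a x^2 + b x`, µg/ml.
#' @examples
#' apply_calibration(quadratic_calibration(-5.9, 9.23), 1)  # 3.33
#' @export
apply_calibration <- function(calib, x) {
  stopifnot(inherits(calib, "quadratic_calibration"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("invalid signal: calibration input must be finite and non-negative",
         call. = FALSE)
  }
  calib$a * x^2 + calib$b * x
}

#' Invert a calibration on its ascending branch
#'
#' Returns the signal `x` on the ascending branch (the smaller root,
#' `x` in `[0, b/(2|a|)]` for `a < 0`) such that `a x^2 + b x = y`.
#'
#' @param calib A [quadratic_calibration()].
#' @param y Lung concentrations, µg/ml; non-negative, and for `a < 0` at most
#'   the vertex value `b^2/(4|a|)`.
#' @return Signal values; round-trips through [apply_calibration()] to better
#'   than 1e-9 relative.
#' @examples
#' invert_calibration(quadratic_calibration(-5.9, 9.23), 0.864)  # 0.1
#' @export
invert_calibration <- function(calib, y) {
  stopifnot(inherits(calib, "quadratic_calibration"))
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("invalid concentration: must be finite and non-negative", call. = FALSE)
  }
  vmax <- calibration_vertex(calib)
  if (any(y > vmax)) {
    stop(sprintf("non-invertible: y exceeds the calibration's attainable maximum %.6g ug/ml",
                 vmax), call. = FALSE)
  }
  if (calib$a == 0) return(y / calib$b)
  disc <- calib$b^2 + 4 * calib$a * y
  disc[disc < 0] <- 0  # roundoff at the vertex
  # ascending-branch root, written stably for either sign of a
  (-calib$b + sqrt(disc)) / (2 * calib$a)
}

#' Fit a zero-intercept quadratic calibration by least squares
#'
#' Ordinary least squares of `y` on the intercept-free basis `(x^2, x)`.
#' Recovers the generating coefficients exactly when `y` is exactly quadratic
#' in `x`.
#'
#' @param x Signal values (length >= 3, not all identical).
#' @param y Concentration values, same length.
#' @param channel Channel label to attach, `"ppb"` or `"volt"`.
#' @return A [quadratic_calibration()]; if the fitted `b` is not positive the
#'   coefficients are still returned, wrapped without the ascending-branch
#'   guarantee (as a plain list) only when `b <= 0` would be rejected -- in
#'   that case an error is raised naming the degenerate fit.
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' fit_calibration(x, -5.9 * x^2 + 9.23 * x)
#' @export
fit_calibration <- function(x, y, channel = c("ppb", "volt")) {
  channel <- match.arg(channel)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length x and y with at least 3 points", call. = FALSE)
  }
  X <- cbind(x2 = x^2, x = x)
  qx <- qr(X)
  if (qx$rank < 2L) {
    stop("rank error: degenerate design (signal values carry no quadratic contrast)",
         call. = FALSE)
  }
  ab <- qr.coef(qx, y)
  if (all(abs(y) < 1e-300)) ab[] <- 0
  if (ab[["x"]] <= 0 && any(y != 0)) {
    stop(sprintf("degenerate calibration fit: linear coefficient b = %.6g is not positive",
                 ab[["x"]]), call. = FALSE)
  }
  if (all(y == 0)) {
    return(structure(list(a = 0, b = 0, channel = channel),
                     class = "quadratic_calibration"))
  }
  quadratic_calibration(ab[["x2"]], ab[["x"]], channel)
}
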