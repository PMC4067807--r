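#' Coefficient of determination
#'
#' Centered R-squared, `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y Observed (response) values; must not be constant.
#' @param yhat Predicted values, same length.
#' @return R-squared, dimensionless.
#' @examples
#' r_squared(1:10, 1:10)  # 1
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L) {
    stop("need equal-length y and yhat with at least 2 points", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) {
    stop("undefined R-squared: response is constant", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / sst
}

#' Specification of a lung-model fit
#'
#' Declares which observation model links plasma to breath, which parameters
#' are estimated and which are held fixed, and the optimizer settings.
#' Model parameters are: `k1L`, `kL1` (lung-compartment model), `ke0lung`
#' (delay model), and the calibration coefficients `a`, `b` (any model).
#' The calibration pair must be either jointly free (it is then solved by
#' inner zero-intercept linear least squares at each outer iteration) or
#' jointly fixed.
#'
#' @param model_kind One of `"lung_compartment"`, `"delay"`, `"static"`.
#'   `"static"` has no dynamic parameters: the breath signal is calibrated
#'   directly against plasma (the hysteresis baseline).
#' @param free Character vector of free parameter names.
#' @param fixed Named list of fixed parameter values (the remaining ones).
#' @param start Named list of start values for free dynamic parameters;
#'   defaults to 0.1 /min for any unspecified rate constant.
#' @param lcc0 Initial lung concentration passed to the dynamic model.
#' @param multi_start Number of deterministic multi-starts (geometric
#'   perturbations of `start`).
#' @param reltol,maxit Optimizer tolerance and iteration budget.
#' @return An object of class `fit_spec`.
#' @examples
#' fit_spec("delay", free = c("ke0lung", "a", "b"))
#' @export
fit_spec <- function(model_kind = c("lung_compartment", "delay", "static"),
                     free = character(), fixed = list(), start = list(),
                     lcc0 = 0, multi_start = 5L, reltol = 1e-8, maxit = 1e4) {
  model_kind <- match.arg(model_kind)
  dyn_all <- switch(model_kind,
                    lung_compartment = c("k1L", "kL1"),
                    delay = "ke0lung",
                    static = character())
  all_par <- c(dyn_all, "a", "b")
  if (!all(free %in% all_par)) {
    stop(sprintf("unknown free parameter(s) for model '%s': %s", model_kind,
                 paste(setdiff(free, all_par), collapse = ", ")), call. = FALSE)
  }
  calib_free <- c("a", "b") %in% free
  if (xor(calib_free[1L], calib_free[2L])) {
    stop("calibration coefficients a and b must be jointly free or jointly fixed",
         call. = FALSE)
  }
  need_fixed <- setdiff(all_par, free)
  if (!all(need_fixed %in% names(fixed))) {
    stop(sprintf("parameters neither free nor fixed: %s",
                 paste(setdiff(need_fixed, names(fixed)), collapse = ", ")),
         call. = FALSE)
  }
  dyn_free <- intersect(dyn_all, free)
  st <- rep(0.1, length(dyn_free)); names(st) <- dyn_free
  st[names(start)[names(start) %in% dyn_free]] <-
    unlist(start[names(start) %in% dyn_free])
  if (any(st <= 0)) stop("start values for rate constants must be positive", call. = FALSE)
  structure(list(model_kind = model_kind, free = free, fixed = fixed,
                 dyn_free = dyn_free, calib_free = all(calib_free),
                 start = st, lcc0 = lcc0, multi_start = as.integer(multi_start),
                 reltol = reltol, maxit = maxit),
            class = "fit_spec")
}

# lung series values under a named dynamic parameter vector
model_response <- function(model_kind, plasma, theta, lcc0) {
  switch(model_kind,
         lung_compartment = series_values(lung_compartment_series(
           plasma, lung_compartment_params(theta[["k1L"]], theta[["kL1"]]), lcc0)),
         delay = series_values(delay_series(
           plasma, delay_params(theta[["ke0lung"]]), lcc0)),
         static = series_values(plasma))
}

# deterministic multi-start factors, centred on 1, geometric spread
start_factors <- function(n_starts, n_par) {
  base <- c(1, 0.5, 2, 0.25, 4, 1/3, 3, 0.1, 10)
  f <- base[seq_len(min(n_starts, length(base)))]
  if (n_par == 1L) return(matrix(f, ncol = 1L))
  # alternate the perturbation pattern across parameters
  m <- cbind(f, rev(f))[, seq_len(n_par), drop = FALSE]
  m[1L, ] <- 1
  m
}

#' Fit a lung observation model to plasma and breath series
#'
#' Joint estimation of the dynamic lung-model parameters and (optionally) the
#' zero-intercept quadratic calibration, by maximizing the coefficient of
#' determination between the modelled lung concentration `y(t; theta)` and the
#' calibrated breath signal `a x_t^2 + b x_t`.  Equivalently the
#' normalized residual sum of squares `SSE/SStot` is minimized; when the
#' calibration is free it is profiled out by inner zero-intercept linear least
#' squares at every outer iteration, so the outer search runs only over the
#' log-transformed rate constants (Nelder-Mead with a deterministic
#' multi-start set; golden-section/Brent when a single rate constant is free).
#'
#' For the lung-compartment model with both `k1L` and the calibration free the
#' objective is invariant under the joint rescaling
#' `(k1L, a, b) -> (c k1L, a/c, b/c)`; the result is then flagged
#' `scale_degenerate` and one representative optimum is returned.
#'
#' @param plasma Plasma-channel [conc_series()] on a 1-min grid.
#' @param breath Breath signal [conc_series()] (`ppb` or `volt`) on the same grid.
#' @param spec A [fit_spec()].
#' @return An object of class `fit_result`: list with `parameters` (all model
#'   parameters, estimated and fixed), `r2`, `sse` ((µg/ml)^2), `residuals`
#'   (data frame `time_min`, `residual` of `y - yhat`), `fitted` (data frame
#'   with `y` = modelled lung and `yhat` = calibrated breath), `converged`,
#'   `scale_degenerate`, `model_kind`, and `n`.
#' @examples
#' cp <- conc_series(1:60, pmin(3, 0.2 * (1:60)), "plasma")
#' lung <- delay_series(cp, delay_params(0.27))
#' x <- invert_calibration(quadratic_calibration(-4.2, 7.14), series_values(lung))
#' breath <- conc_series(1:60, x, "ppb")
#' fit <- fit_model(cp, breath, fit_spec("delay", free = c("ke0lung", "a", "b")))
#' fit$parameters$ke0lung
#' @export
fit_model <- function(plasma, breath, spec) {
  stopifnot(inherits(plasma, "conc_series"), inherits(breath, "conc_series"),
            inherits(spec, "fit_spec"))
  check_same_grid(plasma, breath)
  x <- series_values(breath)
  X <- cbind(x^2, x)
  if (qr(X)$rank < 2L) {
    stop("rank error: degenerate breath signal (no quadratic contrast)", call. = FALSE)
  }

  fixed_ab <- if (!spec$calib_free) c(spec$fixed$a, spec$fixed$b) else NULL
  eval_theta <- function(theta) {
    y <- model_response(spec$model_kind, plasma, theta, spec$lcc0)
    sst <- sum((y - mean(y))^2)
    if (!is.finite(sst) || sst <= 1e-12 * max(1, sum(y^2))) {
      return(list(obj = 1e6, y = y, ab = c(NA_real_, NA_real_)))
    }
    ab <- if (spec$calib_free) qr.coef(qr(X), y) else fixed_ab
    sse <- sum((y - X %*% ab)^2)
    list(obj = sse / sst, y = y, ab = ab)
  }

  converged <- TRUE
  theta <- NULL
  if (length(spec$dyn_free) == 0L) {
    theta <- unlist(spec$fixed[setdiff(names(spec$fixed), c("a", "b"))])
    best <- eval_theta(theta)
    if (best$obj >= 1e6) stop("undefined R-squared: model response is constant", call. = FALSE)
  } else {
    obj_log <- function(lp) {
      theta <- exp(lp); names(theta) <- spec$dyn_free
      theta <- c(theta, unlist(spec$fixed[setdiff(names(spec$fixed), c("a", "b"))]))
      eval_theta(theta)$obj
    }
    facs <- start_factors(spec$multi_start, length(spec$dyn_free))
    best_lp <- NULL; best_val <- Inf; best_conv <- FALSE
    for (s in seq_len(nrow(facs))) {
      lp0 <- log(spec$start * facs[s, ])
      if (length(spec$dyn_free) == 1L) {
        oo <- stats::optimize(obj_log, lower = lp0 - log(1e3), upper = lp0 + log(1e3),
                              tol = 1e-10)
        op <- list(par = oo$minimum, value = oo$objective, convergence = 0L)
      } else {
        op <- stats::optim(lp0, obj_log, method = "Nelder-Mead",
                           control = list(reltol = spec$reltol, maxit = spec$maxit))
      }
      if (op$value < best_val) {
        best_val <- op$value; best_lp <- op$par; best_conv <- op$convergence == 0L
      }
    }
    # polish from the best start
    if (length(spec$dyn_free) > 1L) {
      op <- stats::optim(best_lp, obj_log, method = "Nelder-Mead",
                         control = list(reltol = spec$reltol, maxit = spec$maxit))
      if (op$value <= best_val) {
        best_val <- op$value; best_lp <- op$par; best_conv <- op$convergence == 0L
      }
    }
    converged <- best_conv
    theta <- exp(best_lp); names(theta) <- spec$dyn_free
    theta <- c(theta, unlist(spec$fixed[setdiff(names(spec$fixed), c("a", "b"))]))
    best <- eval_theta(theta)
  }

  y <- best$y
  yhat <- as.numeric(X %*% best$ab)
  sse <- sum((y - yhat)^2)
  r2 <- 1 - best$obj
  if (is.null(theta)) theta <- numeric()
  pars <- stats::setNames(as.list(as.numeric(theta)), names(theta))
  pars$a <- unname(best$ab[1L]); pars$b <- unname(best$ab[2L])
  scale_deg <- spec$model_kind == "lung_compartment" &&
    ("k1L" %in% spec$dyn_free) && spec$calib_free

  structure(list(
    model_kind = spec$model_kind,
    parameters = pars,
    r2 = r2,
    sse = sse,
    residuals = data.frame(time_min = series_times(plasma), residual = y - yhat),
    fitted = data.frame(time_min = series_times(plasma), y = y, yhat = yhat),
    converged = converged,
    scale_degenerate = scale_deg,
    n = length(y)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s, n=%d\n", x$model_kind, x$n))
  p <- unlist(x$parameters)
  cat("  parameters:", paste(sprintf("%s=%.6g", names(p), p), collapse = ", "), "\n")
  cat(sprintf("  R2 = %.6f, SSE = %.6g, converged = %s%s\n", x$r2, x$sse, x$converged,
              if (isTRUE(x$scale_degenerate)) " [scale-degenerate]" else ""))
  invisible(x)
}

#' Direct (static) correlation between plasma and breath
#'
#' The hysteresis baseline: the breath signal is calibrated directly against
#' the plasma concentration with a zero-intercept quadratic, ignoring any lag.
#' Its R-squared is low whenever the observation lags the plasma.
#'
#' @param plasma Plasma-channel [conc_series()].
#' @param breath Breath signal [conc_series()] on the same grid.
#' @return A `fit_result` with `model_kind = "static"`.
#' @examples
#' cp <- conc_series(1:40, c(seq(0.1, 2, length.out = 20), seq(2, 0.1, length.out = 20)), "plasma")
#' breath <- conc_series(1:40, series_values(cp) / 7, "ppb")
#' direct_correlation(cp, breath)$r2  # 1: no lag
#' @export
direct_correlation <- function(plasma, breath) {
  fit_model(plasma, breath, fit_spec("static", free = c("a", "b")))
}

#' Plasma-breath hysteresis data and loop area
#'
#' Pairs the plasma and breath series in time order and summarizes the
#' hysteresis with the signed shoelace area of the closed (plasma, breath)
#' trajectory.  A static (lag-free) observation traces a curve of zero
#' enclosed area; a delayed observation opens a loop whose sign encodes the
#' lag direction.
#'
#' @param plasma Plasma-channel [conc_series()].
#' @param breath Breath [conc_series()] on the same grid.
#' @return A data frame of class `hysteresis_data` with columns `time_min`,
#'   `plasma`, `breath` and attribute `loop_area` (see [loop_area()]).
#' @examples
#' cp <- conc_series(1:40, c(seq(0, 2, length.out = 20), seq(2, 0, length.out = 20)), "plasma")
#' h <- hysteresis_data(cp, delay_series(cp, delay_params(0.27)))
#' loop_area(h)
#' @export
hysteresis_data <- function(plasma, breath) {
  stopifnot(inherits(plasma, "conc_series"), inherits(breath, "conc_series"))
  check_same_grid(plasma, breath)
  px <- series_values(plasma); bx <- series_values(breath)
  # signed shoelace area over the closed polygon (last vertex joined to first)
  xs <- c(px, px[1L]); ys <- c(bx, bx[1L])
  area <- 0.5 * sum(xs[-length(xs)] * ys[-1L] - xs[-1L] * ys[-length(ys)])
  structure(data.frame(time_min = series_times(plasma), plasma = px, breath = bx),
            loop_area = area, class = c("hysteresis_data", "data.frame"))
}

#' @rdname hysteresis_data
#' @param h A `hysteresis_data` object.
#' @export
loop_area <- function(h) {
  stopifnot(inherits(h, "hysteresis_data"))
  attr(h, "loop_area")
}
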