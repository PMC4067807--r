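#' Breath-study protocol
#'
#' Defines a single-patient breath-monitoring acquisition: a plasma-targeting
#' TCI induction/maintenance window followed by a decay tail, sampled once per
#' minute.  The default protocol mirrors the study conditions the package's
#' recovery experiments assume: 346 min of acquisition at one sample per
#' minute, TCI from t = 0 to t = 330 min, an 80-kg patient.  The default
#' plasma target is 2 µg/ml, which keeps every lung concentration safely on
#' the invertible ascending branch of the bundled calibrations; the clinical
#' target of 3 µg/ml can be requested explicitly for plasma-only simulation.
#'
#' @param weight Body mass, kg.
#' @param target TCI plasma target, µg/ml.
#' @param t_start,t_stop TCI window, minutes.
#' @param duration Total acquisition, minutes (>= `t_stop`).
#' @param sampling_interval Sampling cadence, minutes (1 for breath-by-breath
#'   IMS acquisition; the lung-compartment model requires 1).
#' @return An object of class `study_protocol`.
#' @examples
#' default_protocol()
#' @export
study_protocol <- function(weight = 80, target = 2, t_start = 0, t_stop = 330,
                           duration = 346, sampling_interval = 1) {
  if (!(t_start < t_stop && t_stop <= duration)) {
    stop("invalid protocol: need t_start < t_stop <= duration", call. = FALSE)
  }
  if (sampling_interval <= 0) stop("sampling interval must be positive", call. = FALSE)
  structure(list(weight = weight, target = target, t_start = t_start,
                 t_stop = t_stop, duration = duration,
                 sampling_interval = sampling_interval),
            class = "study_protocol")
}

#' @rdname study_protocol
#' @export
default_protocol <- function() study_protocol()

#' Saturating instrument-response model for the volt channel
#'
#' An explicitly synthetic stand-in for the nonlinear response of an ion
#' mobility spectrometer: peak intensity in volt as a saturating hyperbola of
#' the breath mixing ratio in ppb, `v = vmax * x / (khalf + x)` -- strictly
#' monotone, zero at zero, bounded by `vmax`.
#'
#' @param vmax Saturation voltage, V.
#' @param khalf Half-saturation signal, ppb.
#' @return An object of class `ims_response_model`.
#' @examples
#' ppb_to_volt(ims_response_model(), 0.5)  # vmax/2
#' @export
ims_response_model <- function(vmax = 0.8, khalf = 0.5) {
  if (!(vmax > 0 && khalf > 0)) stop("vmax and khalf must be positive", call. = FALSE)
  structure(list(vmax = vmax, khalf = khalf), class = "ims_response_model")
}

#' @rdname ims_response_model
#' @param ims An `ims_response_model`.
#' @param x Breath signal in ppb; non-negative.
#' @export
ppb_to_volt <- function(ims, x) {
  stopifnot(inherits(ims, "ims_response_model"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("invalid signal: ppb input must be finite and non-negative", call. = FALSE)
  }
  ims$vmax * x / (ims$khalf + x)
}

#' Multiplicative measurement-noise model
#'
#' Signal-proportional Gaussian noise, `x * (1 + e)`, `e ~ N(0, cv^2)`,
#' applied to the breath signal channels only, with a seeded generator so
#' that studies are exactly reproducible.
#'
#' @param cv Coefficient of variation (e.g. 0.05 for 5 percent); non-negative.
#' @param seed Integer RNG seed.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(0.05, seed = 1)
#' @export
noise_model <- function(cv = 0.05, seed = 1L) {
  if (!(is.numeric(cv) && length(cv) == 1L && cv >= 0)) {
    stop("`cv` must be a single non-negative number", call. = FALSE)
  }
  structure(list(cv = cv, seed = as.integer(seed)), class = "noise_model")
}

# evaluate code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a complete synthetic breath-monitoring study
#'
#' Builds the full observation chain the analysis assumes, in reverse: a TCI
#' plasma profile (Marsh model), a lung concentration series from the chosen
#' observation model, a noiseless ppb breath signal obtained by inverting the
#' calibration on its ascending branch, a volt channel through the synthetic
#' instrument response, and seeded multiplicative noise on both signal
#' channels.  The generating truth is recorded so any study can be
#' regenerated bit-identically.
#'
#' @param protocol A [study_protocol()].
#' @param model_kind `"delay"` or `"lung_compartment"`.
#' @param dynamic_params A [delay_params()] or [lung_compartment_params()]
#'   matching `model_kind`.
#' @param calib A [quadratic_calibration()] for the ppb channel.
#' @param ims An [ims_response_model()] for the volt channel.
#' @param noise A [noise_model()].
#' @param lcc0 Initial lung concentration, µg/ml.
#' @return An object of class `synthetic_study`: list with `plasma`, `lung`,
#'   `breath_ppb`, `breath_volt` ([conc_series()] on a shared grid) and
#'   `truth` (everything needed by [regenerate_study()]).
#' @examples
#' st <- generate_study(study_protocol(duration = 60, t_stop = 50),
#'                      "delay", delay_params(0.27),
#'                      quadratic_calibration(-4.2, 7.14),
#'                      noise = noise_model(0, seed = 1))
#' @export
generate_study <- function(protocol = default_protocol(),
                           model_kind = c("delay", "lung_compartment"),
                           dynamic_params,
                           calib,
                           ims = ims_response_model(),
                           noise = noise_model(),
                           lcc0 = 0) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(protocol, "study_protocol"),
            inherits(calib, "quadratic_calibration"),
            inherits(ims, "ims_response_model"),
            inherits(noise, "noise_model"))
  if (abs(protocol$sampling_interval - 1) > 1e-12 && model_kind == "lung_compartment") {
    stop("the lung-compartment model requires 1-min sampling", call. = FALSE)
  }
  params <- marsh_parameters(protocol$weight)
  tci <- run_tci(params,
                 tci_protocol(protocol$target, protocol$t_start, protocol$t_stop),
                 duration = protocol$duration)
  plasma <- tci$plasma
  lung <- switch(model_kind,
                 delay = delay_series(plasma, dynamic_params, lcc0),
                 lung_compartment = lung_compartment_series(plasma, dynamic_params, lcc0))
  vmax <- calibration_vertex(calib)
  peak <- max(series_values(lung))
  if (peak > vmax) {
    stop(sprintf(paste0("protocol-range error: lung concentration %.6g ug/ml exceeds ",
                        "the calibration's attainable maximum %.6g ug/ml; ",
                        "lower the plasma target"), peak, vmax), call. = FALSE)
  }
  x0 <- invert_calibration(calib, series_values(lung))
  v0 <- ppb_to_volt(ims, x0)
  n <- length(x0)
  eps <- with_local_seed(noise$seed, list(ppb = stats::rnorm(n, 0, 1),
                                          volt = stats::rnorm(n, 0, 1)))
  tgrid <- series_times(plasma)
  breath_ppb <- conc_series(tgrid, x0 * (1 + noise$cv * eps$ppb), "ppb")
  breath_volt <- conc_series(tgrid, v0 * (1 + noise$cv * eps$volt), "volt")
  truth <- list(protocol = protocol, model_kind = model_kind,
                dynamic_params = dynamic_params, calib = calib, ims = ims,
                noise = noise, lcc0 = lcc0)
  structure(list(plasma = plasma, lung = lung, breath_ppb = breath_ppb,
                 breath_volt = breath_volt, truth = truth),
            class = "synthetic_study")
}

#' @rdname generate_study
#' @param truth The `truth` element of a `synthetic_study`.
#' @export
regenerate_study <- function(truth) {
  generate_study(truth$protocol, truth$model_kind, truth$dynamic_params,
                 truth$calib, truth$ims, truth$noise, truth$lcc0)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> model=%s, %d samples, target %.3g ug/ml, cv=%g, seed=%d\n",
              x$truth$model_kind, nrow(x$plasma), x$truth$protocol$target,
              x$truth$noise$cv, x$truth$noise$seed))
  invisible(x)
}
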