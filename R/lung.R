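#' Lung-compartment model parameters
#'
#' Rate constants of the added two-compartment lung observation model:
#' plasma drives the lung compartment at `k1L` and the lung empties back at
#' `kL1` (both 1/min).  `v_lung` (L) and `cl_lung` (L/min) may be carried as
#' descriptive metadata, but the dynamics use `k1L` and `kL1` directly.
#'
#' @param k1L Plasma-to-lung rate constant, 1/min; positive.
#' @param kL1 Lung-to-plasma rate constant, 1/min; positive.
#' @param v_lung Optional lung-compartment volume of distribution, L.
#' @param cl_lung Optional lung clearance, L/min.
#' @return An object of class `lung_compartment_params`.
#' @examples
#' lung_compartment_params(0.209, 0.138)
#' @export
lung_compartment_params <- function(k1L, kL1, v_lung = NULL, cl_lung = NULL) {
  if (!(is.numeric(k1L) && length(k1L) == 1L && k1L > 0) ||
      !(is.numeric(kL1) && length(kL1) == 1L && kL1 > 0)) {
    stop("invalid parameters: k1L and kL1 must be single positive numbers (1/min)",
         call. = FALSE)
  }
  if (!is.null(v_lung) && v_lung <= 0) stop("v_lung must be positive", call. = FALSE)
  if (!is.null(cl_lung) && cl_lung <= 0) stop("cl_lung must be positive", call. = FALSE)
  structure(list(k1L = k1L, kL1 = kL1, v_lung = v_lung, cl_lung = cl_lung),
            class = "lung_compartment_params")
}

#' Plasma-breath equilibration (delay) parameters
#'
#' The single first-order rate constant `ke0lung` (1/min) governing
#' equilibration between plasma and the lung/breath concentration, in the
#' spirit of the classical effect-compartment ke0.
#'
#' @param ke0lung Equilibration rate constant, 1/min; positive.
#' @return An object of class `delay_params`.
#' @examples
#' delay_params(0.27)
#' @export
delay_params <- function(ke0lung) {
  if (!(is.numeric(ke0lung) && length(ke0lung) == 1L && is.finite(ke0lung) &&
        ke0lung > 0)) {
    stop("invalid parameter: `ke0lung` must be a single positive number (1/min)",
         call. = FALSE)
  }
  structure(list(ke0lung = ke0lung), class = "delay_params")
}

#' Lung-compartment concentration series (difference-equation model)
#'
#' Maps a plasma series to a lung-compartment concentration series by the
#' per-minute difference equation
#' `LCC(t+1) = LCC(t) + k1L * PPC(t) - kL1 * LCC(t)`,
#' seeded with `lcc0` at the first grid point.  The update is defined at
#' 1-minute steps only; series on any other grid are rejected.
#'
#' @param plasma A plasma-channel [conc_series()] on a 1-min grid.
#' @param params A [lung_compartment_params()] object.
#' @param lcc0 Initial lung concentration at the first grid point, µg/ml
#'   (default 0: drug-naive).
#' @return A lung-channel [conc_series()] on the same grid.
#' @examples
#' cp <- conc_series(1:10, rep(3, 10), "plasma")
#' lung_compartment_series(cp, lung_compartment_params(0.209, 0.138))
#' @export
lung_compartment_series <- function(plasma, params, lcc0 = 0) {
  stopifnot(inherits(plasma, "conc_series"), inherits(params, "lung_compartment_params"))
  if (abs(series_dt(plasma) - 1) > 1e-9) {
    stop("grid error: the lung-compartment difference equation requires a 1-min grid; resample upstream",
         call. = FALSE)
  }
  ppc <- series_values(plasma)
  n <- length(ppc)
  lcc <- numeric(n)
  lcc[1L] <- lcc0
  for (i in seq_len(n - 1L)) {
    lcc[i + 1L] <- lcc[i] + params$k1L * ppc[i] - params$kL1 * lcc[i]
  }
  if (any(lcc < 0)) {
    stop("lung-compartment series went negative; check rate constants (need kL1 <= 1) and inputs",
         call. = FALSE)
  }
  conc_series(series_times(plasma), lcc, "lung")
}

#' First-order delay (equilibration) concentration series
#'
#' Maps a plasma series to a lung/breath-equilibrated series by the standard
#' effect-compartment discretization
#' `LCC(t+dt) = PPC(t) + (LCC(t) - PPC(t)) * exp(-ke0lung * dt)`,
#' which for constant plasma matches the continuous solution
#' `LCC(t) = Cp + (lcc0 - Cp) exp(-ke0lung t)` exactly at the grid points.
#'
#' @param plasma A plasma-channel [conc_series()] on a uniform grid.
#' @param params A [delay_params()] object.
#' @param lcc0 Initial lung concentration at the first grid point, µg/ml.
#' @return A lung-channel [conc_series()] on the same grid.
#' @examples
#' cp <- conc_series(1:10, rep(3, 10), "plasma")
#' delay_series(cp, delay_params(0.27))
#' @export
delay_series <- function(plasma, params, lcc0 = 0) {
  stopifnot(inherits(plasma, "conc_series"), inherits(params, "delay_params"))
  dt <- series_dt(plasma)
  f <- exp(-params$ke0lung * dt)
  ppc <- series_values(plasma)
  n <- length(ppc)
  lcc <- numeric(n)
  lcc[1L] <- lcc0
  for (i in seq_len(n - 1L)) {
    lcc[i + 1L] <- ppc[i] + (lcc[i] - ppc[i]) * f
  }
  conc_series(series_times(plasma), lcc, "lung")
}

#' Steady-state lung concentration of the lung-compartment model
#'
#' Fixed point of the per-minute lung update under constant plasma
#' concentration `cp`: `cp * k1L / kL1`.
#'
#' @param params A [lung_compartment_params()] object.
#' @param cp Constant plasma concentration, µg/ml.
#' @return Steady-state lung concentration, µg/ml.
#' @examples
#' steady_state_lung(lung_compartment_params(0.209, 0.138), 3)  # 4.543
#' @export
steady_state_lung <- function(params, cp) {
  stopifnot(inherits(params, "lung_compartment_params"))
  if (params$kL1 == 0) stop("division error: kL1 must be nonzero", call. = FALSE)
  cp * params$k1L / params$kL1
}
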