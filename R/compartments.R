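#' Compartment state of the three-compartment model
#'
#' Drug amounts in the central and the two peripheral compartments at a given
#' time.  Amounts are in mg, so that the plasma concentration `A1 / V1` comes
#' out directly in mg/L, i.e. the clinical unit of micrograms per millilitre.
#'
#' @param t Time in minutes.
#' @param A1,A2,A3 Drug amounts in mg; must be non-negative.
#' @return An object of class `compartment_state`.
#' @examples
#' compartment_state(0, 0, 0, 0)
#' @export
compartment_state <- function(t = 0, A1 = 0, A2 = 0, A3 = 0) {
  A <- c(A1 = A1, A2 = A2, A3 = A3)
  if (!all(is.finite(c(t, A)))) stop("state must be finite", call. = FALSE)
  if (any(A < 0)) stop("compartment amounts must be non-negative", call. = FALSE)
  structure(list(t = t, A = A), class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf("t = %g min: A1 = %.6g, A2 = %.6g, A3 = %.6g mg\n",
              x$t, x$A[1L], x$A[2L], x$A[3L]))
  invisible(x)
}

# First-order rate matrix of the mammillary 3-compartment system,
# d(A)/dt = M A + rate * e1.
rate_matrix <- function(params) {
  with(params, matrix(c(
    -(k10 + k12 + k13), k21,  k31,
    k12,               -k21,  0,
    k13,                0,   -k31
  ), nrow = 3L, byrow = TRUE))
}

# Exact constant-input propagator over a step dt:
#   A(t+dt) = E %*% A(t) + rate * w,
# with E = expm(M dt) via eigendecomposition (the Marsh matrix has three
# distinct negative eigenvalues) and w = M^{-1} (E - I) e1.
# Returns a closure caching (E, w) per distinct dt.
make_propagator <- function(params) {
  M <- rate_matrix(params)
  eg <- eigen(M)
  V <- eg$vectors
  lam <- eg$values
  Vinv <- solve(V)
  Vinv_e1 <- Vinv[, 1L]
  cache <- new.env(parent = emptyenv())
  function(dt) {
    key <- sprintf("%.17g", dt)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ed <- exp(lam * dt)
    E <- Re(V %*% (ed * Vinv))
    # M^{-1}(E - I) e1 = V diag((e^{lam dt} - 1)/lam) V^{-1} e1
    w <- Re(V %*% ((ed - 1) / lam * Vinv_e1))
    out <- list(E = E, w = as.numeric(w))
    cache[[key]] <- out
    out
  }
}

#' Advance the three-compartment system by one exact step
#'
#' Propagates the linear system
#' `dA1/dt = rate - (k10+k12+k13) A1 + k21 A2 + k31 A3`,
#' `dA2/dt = k12 A1 - k21 A2`, `dA3/dt = k13 A1 - k31 A3`
#' over a step of `dt` minutes under a constant infusion rate, using the
#' closed-form constant-input update of the linear system (matrix exponential
#' via eigendecomposition), not a numerical integrator.
#'
#' @param state A [compartment_state()].
#' @param rate Constant infusion rate into the central compartment, mg/min;
#'   non-negative.
#' @param dt Step length in minutes; positive.
#' @param params A [marsh_parameters()] object.
#' @return The advanced `compartment_state` at `state$t + dt`.
#' @examples
#' p <- marsh_parameters(100)
#' step_compartments(compartment_state(0, A1 = 1), rate = 0, dt = 1, p)
#' @export
step_compartments <- function(state, rate, dt, params) {
  stopifnot(inherits(state, "compartment_state"), inherits(params, "marsh_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("invalid argument: `dt` must be a single positive number (min)", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop("invalid argument: `rate` must be a single non-negative number (mg/min)",
         call. = FALSE)
  }
  prop <- make_propagator(params)(dt)
  A <- as.numeric(prop$E %*% state$A + rate * prop$w)
  # exact update of a positive system; clip sub-eps negatives from roundoff
  A[A < 0 & A > -1e-12] <- 0
  compartment_state(state$t + dt, A[1L], A[2L], A[3L])
}

#' Piecewise-constant infusion schedule
#'
#' @param t_start,t_end Segment boundaries in minutes.
#' @param rate Infusion rate per segment, mg/min; non-negative.
#' @return A data frame of class `infusion_schedule` with columns
#'   `t_start`, `t_end`, `rate`; segments time-ordered and non-overlapping.
#' @examples
#' infusion_schedule(c(0, 10), c(10, 20), c(100, 20))
#' @export
infusion_schedule <- function(t_start = numeric(), t_end = numeric(), rate = numeric()) {
  n <- length(t_start)
  if (length(t_end) != n || length(rate) != n) {
    stop("schedule columns must have equal length", call. = FALSE)
  }
  sch <- data.frame(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                    rate = as.numeric(rate))
  if (n > 0L) {
    if (any(!is.finite(unlist(sch)))) stop("schedule entries must be finite", call. = FALSE)
    if (any(sch$t_end <= sch$t_start)) {
      stop("schedule error: each segment needs t_end > t_start", call. = FALSE)
    }
    if (any(sch$rate < 0)) stop("schedule error: rates must be non-negative", call. = FALSE)
    o <- order(sch$t_start)
    sch <- sch[o, , drop = FALSE]
    if (n > 1L && any(sch$t_start[-1L] < sch$t_end[-n] - 1e-9)) {
      stop("schedule error: overlapping segments", call. = FALSE)
    }
  }
  rownames(sch) <- NULL
  structure(sch, class = c("infusion_schedule", "data.frame"))
}

# rate active on the interval (t1, t2); 0 outside all segments
segment_rate <- function(schedule, t1, t2) {
  mid <- (t1 + t2) / 2
  i <- which(schedule$t_start - 1e-9 <= mid & mid < schedule$t_end - 1e-9)
  if (length(i) == 0L) 0 else schedule$rate[i[1L]]
}

#' Simulate plasma concentration under an infusion schedule
#'
#' Integrates the three-compartment system exactly over the piecewise-constant
#' schedule and reports the plasma concentration `Cp(t) = A1(t)/V1` (µg/ml)
#' on the requested uniform grid.
#'
#' @param params A [marsh_parameters()] object.
#' @param schedule An [infusion_schedule()].
#' @param grid Uniform, strictly increasing sample times in minutes.
#' @param init Initial [compartment_state()]; defaults to a drug-naive patient
#'   (all amounts zero at t = 0).
#' @return A plasma-channel [conc_series()] on `grid`.
#' @examples
#' p <- marsh_parameters(100)
#' sch <- infusion_schedule(0, 60, 8.1396)
#' cp <- simulate_infusion(p, sch, grid = 1:60)
#' @export
simulate_infusion <- function(params, schedule, grid, init = compartment_state()) {
  stopifnot(inherits(params, "marsh_params"))
  if (!inherits(schedule, "infusion_schedule")) {
    schedule <- do.call(infusion_schedule, as.list(schedule))
  }
  grid <- as.numeric(grid)
  if (length(grid) < 2L) stop("grid needs at least 2 samples", call. = FALSE)
  t0 <- init$t
  if (grid[1L] <= t0) stop("grid must start after the initial state time", call. = FALSE)
  prop <- make_propagator(params)
  breaks <- sort(unique(round(c(t0, grid, schedule$t_start, schedule$t_end), 9)))
  breaks <- breaks[breaks >= t0 & breaks <= grid[length(grid)]]
  A <- init$A
  out <- numeric(length(grid))
  gi <- 1L
  for (k in seq_len(length(breaks) - 1L)) {
    t1 <- breaks[k]; t2 <- breaks[k + 1L]
    r <- segment_rate(schedule, t1, t2)
    pk <- prop(t2 - t1)
    A <- as.numeric(pk$E %*% A + r * pk$w)
    while (gi <= length(grid) && abs(grid[gi] - t2) <= 1e-9) {
      out[gi] <- A[1L] / params$V1
      gi <- gi + 1L
    }
  }
  if (gi <= length(grid)) stop("internal error: grid point not reached", call. = FALSE)
  conc_series(grid, out, "plasma")
}
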