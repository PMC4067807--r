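# Independent oracles and shared fixtures, built in code.

# Explicit forward-Euler integrator for the 3-compartment system.
# Kept deliberately naive and independent of the package's exact propagator.
euler_compartments <- function(params, A0, rate_fun, t_end, dt) {
  k10 <- params$k10; k12 <- params$k12; k21 <- params$k21
  k13 <- params$k13; k31 <- params$k31
  A <- A0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    d1 <- rate_fun(t) - (k10 + k12 + k13) * A[1] + k21 * A[2] + k31 * A[3]
    d2 <- k12 * A[1] - k21 * A[2]
    d3 <- k13 * A[1] - k31 * A[3]
    A <- A + dt * c(d1, d2, d3)
  }
  A
}

# Rate function for a piecewise-constant schedule (left-closed segments).
schedule_rate_fun <- function(schedule) {
  function(t) {
    i <- which(schedule$t_start <= t & t < schedule$t_end)
    if (length(i) == 0) 0 else schedule$rate[i[1]]
  }
}

# Shared noiseless recovery studies (generated once per test run).
.fixtures <- new.env()

delay_study <- function() {
  if (is.null(.fixtures$delay)) {
    .fixtures$delay <- generate_study(
      default_protocol(), "delay", delay_params(0.27),
      quadratic_calibration(-4.2, 7.14, "ppb"),
      noise = noise_model(cv = 0, seed = 1))
  }
  .fixtures$delay
}

lung_study <- function() {
  if (is.null(.fixtures$lung)) {
    .fixtures$lung <- generate_study(
      default_protocol(), "lung_compartment", lung_compartment_params(0.209, 0.138),
      quadratic_calibration(-5.9, 9.23, "ppb"),
      noise = noise_model(cv = 0, seed = 1))
  }
  .fixtures$lung
}
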