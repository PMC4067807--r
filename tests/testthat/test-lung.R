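const_plasma <- function(c, n = 400) conc_series(1:n, rep(c, n), "plasma")

test_that("lung-compartment update: one step and fixed point at the reported rates", {
  par <- lung_compartment_params(0.209, 0.138)
  lcc <- lung_compartment_series(const_plasma(3, 10), par)
  # one application of LCC(t+1) = LCC + k1L*PPC - kL1*LCC from 0
  expect_equal(series_values(lcc)[2], 0.209 * 3)

  # iterated to convergence the update reaches cp * k1L / kL1
  lcc_long <- lung_compartment_series(const_plasma(3, 400), par)
  fp <- (0.209 / 0.138) * 3
  expect_equal(series_values(lcc_long)[400], fp, tolerance = 1e-8)
  expect_equal(steady_state_lung(par, 3), fp)
  expect_equal(fp, 4.543, tolerance = 1e-3)
})

test_that("symmetric rates equilibrate the lung to the plasma concentration", {
  par <- lung_compartment_params(0.2, 0.2)
  lcc <- lung_compartment_series(const_plasma(2.5, 300), par)
  expect_equal(series_values(lcc)[300], 2.5, tolerance = 1e-8)
})

test_that("the per-minute difference equation rejects other grids", {
  half <- conc_series(seq(0.5, 10, by = 0.5), rep(1, 20), "plasma")
  expect_error(lung_compartment_series(half, lung_compartment_params(0.2, 0.1)),
               "grid error")
})

test_that("delay update: one step, equilibrium and fast-tracking limit", {
  expect_equal(series_values(delay_series(const_plasma(3, 5), delay_params(0.27)))[2],
               3 * (1 - exp(-0.27)))
  # lcc0 at the plasma level stays there
  lcc <- delay_series(const_plasma(2, 50), delay_params(0.27), lcc0 = 2)
  expect_equal(series_values(lcc), rep(2, 50))
  # very fast equilibration tracks plasma within one step
  lcc_fast <- delay_series(const_plasma(3, 5), delay_params(50))
  expect_equal(series_values(lcc_fast)[-1], rep(3, 4), tolerance = 1e-6)
})

test_that("delay discretization matches the continuous constant-plasma solution", {
  ke0 <- 0.27; cp <- 3; lcc0 <- 0.5
  for (dt in c(0.5, 1, 2)) {
    tt <- seq(dt, 40, by = dt)
    plasma <- conc_series(tt, rep(cp, length(tt)), "plasma")
    lcc <- series_values(delay_series(plasma, delay_params(ke0), lcc0))
    analytic <- cp + (lcc0 - cp) * exp(-ke0 * (tt - tt[1]))
    expect_equal(lcc, analytic, tolerance = 1e-12)
  }
})

test_that("both observation models are linear in the plasma input", {
  tt <- 1:100
  plasma <- conc_series(tt, 2 * exp(-0.02 * tt) * (1 - exp(-0.3 * tt)), "plasma")
  plasma2 <- conc_series(tt, 2 * series_values(plasma), "plasma")
  lp <- lung_compartment_params(0.209, 0.138)
  dp <- delay_params(0.27)
  expect_equal(2 * series_values(lung_compartment_series(plasma, lp)),
               series_values(lung_compartment_series(plasma2, lp)))
  expect_equal(2 * series_values(delay_series(plasma, dp)),
               series_values(delay_series(plasma2, dp)))
})

test_that("lung lags below plasma during a rise; k1L/kL1 sets the steady excess", {
  rise <- conc_series(1:200, rep(3, 200), "plasma")
  # delay model always approaches from below when starting at 0
  d <- series_values(delay_series(rise, delay_params(0.27)))
  expect_true(all(d[-200] < 3))
  # lung model with k1L/kL1 <= 1 stays below plasma during loading
  l1 <- series_values(lung_compartment_series(rise, lung_compartment_params(0.1, 0.12)))
  expect_true(all(l1 < 3))
  # with k1L/kL1 > 1 the steady lung value exceeds plasma by exactly that ratio
  l2 <- series_values(lung_compartment_series(rise, lung_compartment_params(0.209, 0.138)))
  expect_equal(l2[200] / 3, 0.209 / 0.138, tolerance = 1e-8)
})

test_that("parameter constructors enforce positivity", {
  expect_error(lung_compartment_params(0, 0.1), "positive")
  expect_error(lung_compartment_params(0.1, -1), "positive")
  expect_error(delay_params(0), "positive")
  expect_error(delay_params(-0.2), "positive")
})
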