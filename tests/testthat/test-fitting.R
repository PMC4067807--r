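test_that("r_squared: definition, edge cases and scale invariance", {
  y <- c(1, 2, 3, 5, 8)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  yhat <- y + c(0.1, -0.2, 0, 0.3, -0.1)
  expect_equal(r_squared(3 * y, 3 * yhat), r_squared(y, yhat))
  expect_equal(r_squared(-0.5 * y, -0.5 * yhat), r_squared(y, yhat))
  expect_error(r_squared(rep(2, 5), 1:5), "constant")
  expect_error(r_squared(1:3, 1:4), "equal-length")
})

test_that("joint delay-model fit recovers the generating parameters to < 1%", {
  st <- delay_study()
  fit <- fit_model(st$plasma, st$breath_ppb,
                   fit_spec("delay", free = c("ke0lung", "a", "b")))
  expect_true(fit$converged)
  expect_false(fit$scale_degenerate)
  expect_equal(fit$parameters$ke0lung, 0.27, tolerance = 0.01)
  expect_equal(fit$parameters$a, -4.2, tolerance = 0.01)
  expect_equal(fit$parameters$b, 7.14, tolerance = 0.01)
  expect_gt(fit$r2, 1 - 1e-6)
  expect_lt(fit$sse, 1e-10)
})

test_that("lung-compartment fit with fixed calibration recovers both rate constants", {
  st <- lung_study()
  fit <- fit_model(st$plasma, st$breath_ppb,
                   fit_spec("lung_compartment", free = c("k1L", "kL1"),
                            fixed = list(a = -5.9, b = 9.23)))
  expect_true(fit$converged)
  expect_equal(fit$parameters$k1L, 0.209, tolerance = 0.01)
  expect_equal(fit$parameters$kL1, 0.138, tolerance = 0.01)
  expect_gt(fit$r2, 1 - 1e-6)
})

test_that("inner linear LS with rate constants fixed recovers the calibration exactly", {
  st <- lung_study()
  fit <- fit_model(st$plasma, st$breath_ppb,
                   fit_spec("lung_compartment", free = c("a", "b"),
                            fixed = list(k1L = 0.209, kL1 = 0.138)))
  expect_equal(fit$parameters$b, 9.23, tolerance = 1e-4)
  expect_equal(fit$parameters$a, -5.9, tolerance = 1e-4)
})

test_that("the lung-compartment scale degeneracy is detected and R2-invariant", {
  st <- lung_study()
  fit <- fit_model(st$plasma, st$breath_ppb,
                   fit_spec("lung_compartment", free = c("k1L", "kL1", "a", "b")))
  expect_true(fit$scale_degenerate)

  # any c-scaled solution (c k1L, kL1) with rescaled calibration has the same R2:
  # the modelled lung series scales by c and the inner LS absorbs it exactly
  x <- series_values(st$breath_ppb)
  X <- cbind(x^2, x)
  r2_at <- function(k1L, kL1) {
    y <- series_values(lung_compartment_series(st$plasma,
                                               lung_compartment_params(k1L, kL1)))
    r_squared(y, as.numeric(X %*% qr.coef(qr(X), y)))
  }
  base <- r2_at(0.209, 0.138)
  for (c_ in c(0.5, 2, 5)) expect_equal(r2_at(c_ * 0.209, 0.138), base, tolerance = 1e-9)
})

test_that("inner LS attains an SSE no larger than any externally supplied calibration", {
  st <- delay_study()
  y <- series_values(st$lung)
  x <- series_values(st$breath_ppb)
  X <- cbind(x^2, x)
  sse_inner <- sum((y - X %*% qr.coef(qr(X), y))^2)
  for (ab in list(c(-4.2, 7.14), c(-4, 7), c(-5, 8), c(0, 7.2))) {
    expect_lte(sse_inner, sum((y - X %*% ab)^2) + 1e-12)
  }
})

test_that("multi-start converges to the generating optimum from distant starts", {
  st <- delay_study()
  for (s0 in c(0.02, 0.135, 0.405, 2)) {  # far below to far above the truth
    fit <- fit_model(st$plasma, st$breath_ppb,
                     fit_spec("delay", free = c("ke0lung", "a", "b"),
                              start = list(ke0lung = s0)))
    expect_equal(fit$parameters$ke0lung, 0.27, tolerance = 0.01)
  }
})

test_that("noisy recovery: 5% multiplicative noise leaves ke0lung within 10%", {
  st <- generate_study(default_protocol(), "delay", delay_params(0.27),
                       quadratic_calibration(-4.2, 7.14, "ppb"),
                       noise = noise_model())  # generator defaults: cv 5%, seed 1
  fit <- fit_model(st$plasma, st$breath_ppb,
                   fit_spec("delay", free = c("ke0lung", "a", "b")))
  expect_equal(fit$parameters$ke0lung, 0.27, tolerance = 0.1)
})

test_that("direct correlation: exact for lag-free observation, beaten by the delay fit", {
  st <- delay_study()
  # lag-free: breath is a static (invertible quadratic) map of plasma
  x_static <- invert_calibration(quadratic_calibration(-4.2, 7.14),
                                 series_values(st$plasma) * 0.9)
  breath_static <- conc_series(series_times(st$plasma), x_static, "ppb")
  expect_equal(direct_correlation(st$plasma, breath_static)$r2, 1, tolerance = 1e-9)

  # delayed observation: static baseline is strictly worse than the delay fit
  base <- direct_correlation(st$plasma, st$breath_ppb)
  fit <- fit_model(st$plasma, st$breath_ppb,
                   fit_spec("delay", free = c("ke0lung", "a", "b")))
  expect_lt(base$r2, fit$r2)

  cst <- conc_series(1:10, rep(2, 10), "plasma")
  cbr <- conc_series(1:10, rep(0.3, 10), "ppb")
  expect_error(direct_correlation(cst, cbr), "rank error|constant")
})

test_that("hysteresis loop area: zero when static, signed by lag, antisymmetric in time", {
  tt <- 1:80
  up_down <- c(seq(0.05, 2, length.out = 40), seq(2, 0.05, length.out = 40))
  plasma <- conc_series(tt, up_down, "plasma")
  # static linear observation: trajectory retraces itself, area vanishes
  h0 <- hysteresis_data(plasma, conc_series(tt, up_down / 7, "ppb"))
  expect_lt(abs(loop_area(h0)), 1e-9)

  lagged <- delay_series(plasma, delay_params(0.27))
  h1 <- hysteresis_data(plasma, lagged)
  expect_gt(abs(loop_area(h1)), 0.01)
  # breath below plasma on the rise and above on the fall: the trajectory runs
  # rightwards along the lower branch and back along the upper one, a
  # counterclockwise loop in the (plasma, breath) plane -> positive area
  expect_gt(loop_area(h1), 0)

  rev_plasma <- conc_series(tt, rev(up_down), "plasma")
  rev_breath <- conc_series(tt, rev(series_values(lagged)), "lung")
  expect_equal(loop_area(hysteresis_data(rev_plasma, rev_breath)), -loop_area(h1),
               tolerance = 1e-12)
})

test_that("fit_spec validates parameter bookkeeping", {
  expect_error(fit_spec("delay", free = c("k1L")), "unknown free")
  expect_error(fit_spec("delay", free = c("ke0lung", "a")), "jointly")
  expect_error(fit_spec("delay", free = "ke0lung"), "neither free nor fixed")
  expect_error(fit_spec("delay", free = c("ke0lung", "a", "b"),
                        start = list(ke0lung = -1)), "positive")
})
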