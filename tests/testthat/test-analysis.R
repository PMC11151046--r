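test_that("amplification time interpolates crossings and validates input", {
  tr <- celia_trace(c(0, 10, 20), c(0, 0.4, 1.2))
  res <- amplification_time(tr, list(absolute = 1.0))
  expect_equal(res$at, 17.5)
  expect_true(res$crossed)
  # flat trace never crosses
  flat <- celia_trace(seq(0, 100, 10), rep(0, 11))
  expect_false(amplification_time(flat, list(absolute = 0.5))$crossed)
  # threshold at or below baseline is rejected
  expect_error(amplification_time(tr, list(absolute = -1)), "baseline")
  expect_error(amplification_time(tr, list(fraction_of_max = 1.2)),
               "fraction_of_max")
  expect_error(celia_trace(c(0, 10, 5), c(0, 1, 2)), "strictly increasing")
  # baseline subtraction: constant offset does not move At
  t <- seq(0, 500, 2)
  v <- 10 / (1 + exp(-(t - 250) / 20))
  at0 <- amplification_time(celia_trace(t, v))$at
  at5 <- amplification_time(celia_trace(t, v + 5))$at
  expect_equal(at0, at5, tolerance = 1e-6)
})

test_that("raising the threshold never lowers At on a rising trace", {
  t <- seq(0, 500, 2)
  v <- 10 / (1 + exp(-(t - 250) / 30))
  tr <- celia_trace(t, v)
  ats <- vapply(seq(0.1, 0.9, by = 0.1), function(f)
    amplification_time(tr, list(fraction_of_max = f))$at, numeric(1))
  expect_true(all(diff(ats) > 0))
})

test_that("linear-phase fitting is exact on a capped ramp", {
  t <- seq(0, 300)
  tr <- celia_trace(t, pmin(0.01 * t, 2))
  lf <- linear_phase_fit(tr)
  expect_equal(lf$gain, 0.01, tolerance = 1e-9)
  expect_equal(lf$saturation, 2.0, tolerance = 1e-9)
  expect_equal(lf$window, 198, tolerance = 1e-9)   # 200 * sat_fraction
  expect_equal(lf$r2_fit, 1)
  expect_false(lf$censored)
  # un-capped ramp: censored at trace end, window undefined
  lf2 <- linear_phase_fit(celia_trace(t, 0.01 * t))
  expect_true(lf2$censored)
  expect_true(is.na(lf2$window))
  expect_equal(lf2$saturation, 3, tolerance = 1e-9)
  expect_equal(lf2$gain, 0.01, tolerance = 1e-9)
  expect_error(linear_phase_fit(celia_trace(t, rep(1, length(t)))),
               "rising")
})

test_that("fitted gain scales with the linear template concentration", {
  p <- celia_params()
  gains <- vapply(c(1, 2, 5, 10), function(ato) {
    ts <- simulate_ode(build_linear_module(ato, 125, p,
                                           preactivated_frac = 1), 3000, 2)
    linear_phase_fit(get_trace(ts, "omega"))$gain
  }, numeric(1))
  ratio <- gains / c(1, 2, 5, 10)
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.05)
  # window identity: window ~ s_F * [rT_omega] / gain
  ts <- simulate_ode(build_linear_module(5, 125, p, preactivated_frac = 1),
                     2500, 2)
  lf <- linear_phase_fit(get_trace(ts, "omega"))
  expect_equal(lf$window, p$s_F * 125 / lf$gain, tolerance = 0.05)
})

test_that("endpoint readout interpolates and respects the trace span", {
  t <- seq(0, 1200, 2)
  tr <- celia_trace(t, 0.01 * t)
  expect_equal(endpoint_signal(tr, 1000), 10.0)
  expect_equal(endpoint_signal(tr, 1001), 10.01)      # between samples
  expect_identical(endpoint_signal(tr, 400), tr$values[t == 400])
  expect_error(endpoint_signal(tr, 1300), "outside")
  # non-decreasing in t for an irreversible-reporter trace
  eps <- vapply(c(100, 400, 800, 1200), function(te)
    endpoint_signal(tr, te), numeric(1))
  expect_true(all(diff(eps) >= 0))
})

test_that("endpoint-At regression recovers exact lines and flags degeneracy", {
  at <- c(10, 200, 500, 900)
  fit <- endpoint_at_regression(data.frame(at = at,
                                           endpoint = -0.01 * at + 10))
  expect_equal(fit$slope, -0.01)
  expect_equal(fit$intercept, 10)
  expect_equal(fit$r2, 1)
  # two points are always a perfect (forced) fit
  two <- endpoint_at_regression(data.frame(at = c(1, 2),
                                           endpoint = c(5, 9)))
  expect_equal(two$r2, 1)
  expect_error(endpoint_at_regression(
    data.frame(at = c(5, 5, 5), endpoint = c(1, 2, 3))), "degenerate")
})

test_that("late-At endpoints follow gain * (readout - At - delay)", {
  ats <- c()
  eps <- c()
  for (a0 in c(3e-5, 5e-6, 1e-6)) {
    ts <- simulate_ode(celia_circuit("coupled", alpha0 = a0), 1000, 2)
    ats <- c(ats, amplification_time(get_trace(ts, "alpha"),
                                     list(absolute = 10))$at)
    eps <- c(eps, endpoint_signal(get_trace(ts, "omega"), 1000))
  }
  gain <- 0.1   # k_lin * [alpha_to_omega] at defaults
  delta <- 1000 - ats - eps / gain
  expect_true(all(delta > 0 & delta < 45))
  expect_lt(diff(range(delta)), 5)   # a constant onset delay
})
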