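p_def <- celia_params()

test_that("an empty initiator is a fixed point of the exponential switch", {
  ts <- simulate_ode(build_exponential_module(20, 0, 50, 0), 1000, 10)
  expect_true(all(ts$conc[, "alpha"] == 0))
  expect_true(all(ts$channels[, "alpha"] == 0))
})

test_that("strong pseudotemplate inhibition forces monotone alpha decay", {
  # k_deact * pT = 0.025 > r_exp = 0.017: deactivation beats autocatalysis
  pT <- 5
  net <- build_exponential_module(20, pT, 50, 0.5, p_def)
  ts <- simulate_ode(net, 1000, 2)
  a <- ts$conc[, "alpha"]
  expect_true(all(diff(a) < 0))
  expect_false(
    amplification_time(get_trace(ts, "alpha"), list(absolute = 10))$crossed)
  # cross-check the trajectory against the hand-coded Euler oracle
  orc <- euler_exponential(0.5, pT, 300, dt = 1e-3, p_def)
  i <- ts$times <= 300
  expect_lt(rel_dev(a[i], orc$alpha, floor = 1e-6), 1e-3)
})

test_that("doubling the initiator advances At by ln(2)/r_exp", {
  at_of <- function(a0) {
    ts <- simulate_ode(build_exponential_module(20, 0, 50, a0, p_def),
                       1500, 2)
    amplification_time(get_trace(ts, "alpha"), list(absolute = 10))$at
  }
  shift <- at_of(1e-5) - at_of(2e-5)
  expect_equal(shift, log(2) / p_def$r_exp, tolerance = 0.01)
})

test_that("At is log-linear in the initiator with slope -ln(10)/r_exp", {
  a0s <- 10^seq(-5, -1)
  ats <- vapply(a0s, function(a0) {
    ts <- simulate_ode(build_exponential_module(20, 0, 50, a0, p_def),
                       1500, 2)
    amplification_time(get_trace(ts, "alpha"), list(absolute = 10))$at
  }, numeric(1))
  slope <- unname(coef(stats::lm(ats ~ log10(a0s)))[2])
  expect_equal(slope, -log(10) / p_def$r_exp, tolerance = 0.02)
})

test_that("the converter is a saturating, catalytic microRNA source", {
  # no target, no background initiator: nothing ever fires
  ts0 <- simulate_ode(celia_circuit("assay", target_molar = 0, alpha0 = 0),
                      800, 10)
  expect_true(all(ts0$conc[, "alpha"] == 0))
  # the microRNA is recycled, not consumed
  ts1 <- simulate_ode(celia_circuit("assay", target_molar = 1e-12,
                                    alpha0 = 0), 800, 10)
  expect_equal(ts1$conc[, "miR"], rep(1e-12 * 1e9, length(ts1$times)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # well below K_conv, a tenfold target increase advances At by ln(10)/r_exp
  at_of <- function(c) {
    ts <- simulate_ode(celia_circuit("assay", target_molar = c, alpha0 = 0),
                       1200, 2)
    amplification_time(get_trace(ts, "alpha"), list(absolute = 10))$at
  }
  expect_equal(at_of(1e-13) - at_of(1e-12), log(10) / p_def$r_exp,
               tolerance = 0.02)
  # converters for different microRNAs differ only by label
  expect_identical(simulate_ode(build_converter(10, 1e-12), 100, 10)$conc,
                   simulate_ode(build_converter(10, 1e-12), 100, 10)$conc)
})

test_that("linear-module saturation is set by the reporter pool", {
  # no reporter: no signal even though omega accumulates
  ts <- simulate_ode(build_linear_module(5, 0, p_def,
                                         preactivated_frac = 1), 300, 2)
  expect_true(all(ts$channels[, "omega"] == 0))
  expect_gt(max(ts$conc[, "omega"]), 0)
  # saturation equals s_F * [rT_omega] across reporter levels
  for (rto in c(50, 125, 200)) {
    ts <- simulate_ode(build_linear_module(5, rto, p_def,
                                           preactivated_frac = 1), 2500, 2)
    lf <- linear_phase_fit(get_trace(ts, "omega"))
    expect_equal(lf$saturation, p_def$s_F * rto, tolerance = 0.01)
  }
})

test_that("the inverter stops omega production when alpha fires", {
  # never triggered, leak-free: plain constitutive linear amplification
  p0 <- celia_params(leak_kill = 1e-12)
  net <- compose_networks(build_exponential_module(20, 0, 50, 0, p0),
                          build_inverter_module(2, 50, 2, 200, p0))
  ts <- simulate_ode(net, 3500, 5)
  lf <- linear_phase_fit(get_trace(ts, "omega"))
  expect_false(lf$censored)
  expect_equal(lf$saturation, 200, tolerance = 0.01)
  # saturating alpha from the start: beta is depleted early, endpoint tiny
  pk <- celia_params(k_kill = 2)
  net <- compose_networks(build_exponential_module(20, 0, 50, 50, pk),
                          build_inverter_module(2, 50, 2, 200, pk))
  ts <- simulate_ode(net, 1000, 2)
  expect_lt(endpoint_signal(get_trace(ts, "omega"), 1000), 0.05 * 200)
  expect_lt(ts$conc[nrow(ts$conc), "beta"], 1)
  # leak alone degrades the production rate even without amplification
  net <- compose_networks(build_exponential_module(20, 0, 50, 0, p_def),
                          build_inverter_module(2, 50, 2, 200, p_def))
  ts <- simulate_ode(net, 1000, 2)
  v <- ts$channels[, "omega"]
  slope_early <- (v[ts$times == 200] - v[ts$times == 100]) / 100
  slope_late <- (v[ts$times == 1000] - v[ts$times == 900]) / 100
  # the large beta pool buffers the droop, but the decay must be there
  expect_lt(slope_late, 0.99 * slope_early)
  # and it is leak-driven: without leak the rate is essentially constant
  p0 <- celia_params(leak_kill = 1e-12)
  net0 <- compose_networks(build_exponential_module(20, 0, 50, 0, p0),
                           build_inverter_module(2, 50, 2, 200, p0))
  v0 <- simulate_ode(net0, 1000, 2)$channels[, "omega"]
  s0e <- (v0[ts$times == 200] - v0[ts$times == 100]) / 100
  s0l <- (v0[ts$times == 1000] - v0[ts$times == 900]) / 100
  expect_gt(s0l, 0.999 * s0e)
})

test_that("default kinetics place assay At inside the working range", {
  at_of <- function(c) {
    ts <- simulate_ode(celia_circuit("assay", target_molar = c), 1000, 2)
    amplification_time(get_trace(ts, "alpha"), list(absolute = 10))$at
  }
  at_hi <- at_of(1e-8)    # 10 nM
  at_lo <- at_of(1e-14)   # 10 fM
  expect_gt(at_hi, 50)
  expect_lt(at_lo, 900)
  expect_gt(at_lo, at_hi)
})
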