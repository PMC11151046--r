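test_that("sigmoid evaluation satisfies its defining identities", {
  m <- list(L = 0, H = 10, b = 1, k = 1, x0 = 0)
  expect_equal(sigmoid_eval(m, 0), 5)                 # midpoint with b = 1
  expect_equal(sigmoid_eval(m, 1e6), 10)              # upper asymptote
  expect_equal(sigmoid_eval(m, -1e6), 0)              # lower asymptote
  m2 <- list(L = 1, H = 9, b = 1, k = 2, x0 = -12)
  expect_equal(sigmoid_eval(m2, -12), 1 + 9 / 2)
})

test_that("sigmoid fitting recovers exact and noisy calibration data", {
  true <- list(L = 1, H = 9, b = 1, k = 2, x0 = -12)
  x <- seq(-15, -9, length.out = 8)
  y <- sigmoid_eval(true, x)
  m <- fit_sigmoid(x, y)
  expect_equal(m$L, true$L, tolerance = 1e-4)
  expect_equal(m$H, true$H, tolerance = 1e-4)
  expect_equal(m$k, true$k, tolerance = 1e-4)
  expect_equal(m$x0, true$x0, tolerance = 1e-4)
  expect_lt(m$residual_sd, 1e-6)
  # noisy triplicates: steepness and midpoint recovered within 5%
  withr::with_seed(31, {
    xn <- rep(x, each = 3)
    yn <- sigmoid_eval(true, xn) + rnorm(length(xn), 0, 0.01 * true$H)
    mn <- fit_sigmoid(xn, yn)
    expect_equal(mn$k, true$k, tolerance = 0.05)
    expect_equal(mn$x0, true$x0, tolerance = 0.05)
  })
  # preconditions
  expect_error(fit_sigmoid(c(-12, -11, -10, -9), sigmoid_eval(true,
               c(-12, -11, -10, -9))), ">= 5 distinct")
  expect_error(fit_sigmoid(seq(-12, -10, length.out = 6),
                           sigmoid_eval(true, seq(-12, -10,
                                                  length.out = 6))),
               "3 decades")
})

test_that("sigmoid inversion is the exact inverse on the open band", {
  m <- structure(list(L = 1, H = 9, b = 1, k = 2, x0 = -12,
                      residual_sd = 0), class = "celia_calibration")
  expect_equal(invert_sigmoid(m, 1 + 9 / 2)$x, -12)
  withr::with_seed(5, {
    xs <- runif(100, -14.5, -9.5)
    for (x in xs) {
      inv <- invert_sigmoid(m, sigmoid_eval(m, x))
      expect_identical(inv$flag, "ok")
      expect_equal(inv$x, x, tolerance = 1e-9)
    }
  })
  expect_identical(invert_sigmoid(m, m$L)$flag, "below_range")
  expect_identical(invert_sigmoid(m, m$L + m$H)$flag, "above_range")
})

test_that("LoD follows the blank-mean-plus-three-SD rule and is monotone", {
  m <- structure(list(L = 1, H = 9, b = 1, k = 2, x0 = -12,
                      residual_sd = 0, x_range = c(-15, -9)),
                 class = "celia_calibration")
  # equal blanks: sd = 0, LoD inverts the blank level itself
  ld0 <- lod(m, c(2, 2, 2))
  expect_equal(log10(ld0$lod_molar), invert_sigmoid(m, 2)$x,
               tolerance = 1e-9)
  # worked arithmetic: blanks {1.0, 1.2, 1.4} -> y* = 1.2 + 3*0.2 = 1.8
  ld <- lod(m, c(1.0, 1.2, 1.4))
  expect_equal(ld$y_star, 1.8)
  expect_equal(log10(ld$lod_molar), invert_sigmoid(m, 1.8)$x,
               tolerance = 1e-9)
  # more blank noise never lowers the LoD
  lods <- vapply(c(0.05, 0.1, 0.2, 0.4), function(s)
    lod(m, 2 + c(-s, 0, s))$lod_molar, numeric(1))
  expect_true(all(diff(lods) > 0))
  # blanks at the upper asymptote are an assay failure
  expect_error(lod(m, c(10, 10.2)), "assay failure")
  # blank mean below the invertible band: LoD censored low
  expect_true(lod(m, c(1.0, 1.0))$censored_low)
})

test_that("fold differences are symmetric and censoring-aware", {
  fd <- fold_difference(c(1e-12, 4e-13), c(1e-12, 4e-13))
  expect_equal(fd$mean_fd, 1)
  expect_equal(fd$sd_fd, 0)
  # over- and under-estimation by the same factor are equivalent
  fd2 <- fold_difference(c(2e-12, 5e-13), c(1e-12, 1e-12))
  expect_equal(fd2$fd, c(2, 2))
  # invalid/censored estimates are excluded and counted
  fd3 <- fold_difference(c(1e-12, NA, -1, 3e-12),
                         c(1e-12, 1e-12, 1e-12, 1e-12),
                         flag = c("ok", "below_lod", "ok", "ok"))
  expect_equal(fd3$n_used, 2)
  expect_equal(fd3$n_censored, 2)
  expect_error(fold_difference(1e-12, -1), "positive")
})

test_that("panel fold-difference matches a direct Monte-Carlo oracle", {
  # estimates with lognormal error, sd = 0.3 log10 units
  gen <- function(n, seed) withr::with_seed(seed, {
    truth <- 10^runif(n, -14, -10)
    est <- truth * 10^rnorm(n, 0, 0.3)
    fold_difference(est, truth)$fd
  })
  panel <- gen(54, seed = 21)
  oracle <- gen(1e5, seed = 22)
  # the 54-sample mean sits within ~3 SE of the large-sample oracle mean
  se <- sd(panel) / sqrt(length(panel))
  expect_lt(abs(mean(panel) - mean(oracle)), 3 * se)
  # and the oracle itself matches the closed form 2*exp(a^2/2)*Phi(a)
  a <- 0.3 * log(10)
  expect_equal(mean(oracle), 2 * exp(a^2 / 2) * pnorm(a), tolerance = 0.02)
})

test_that("quantification flags respect range and LoD censoring", {
  m <- structure(list(L = 1, H = 9, b = 1, k = 2, x0 = -12,
                      residual_sd = 0, lod_molar = 1e-13),
                 class = "celia_calibration")
  est <- quantify_endpoints(m, c(0.5, 1.2, 5.5, 10 - 1e-9, 11))
  expect_identical(est$flag,
                   c("below_range", "below_lod", "ok", "above_range",
                     "above_range"))
  expect_true(is.na(est$estimate_molar[1]))
  expect_equal(est$estimate_molar[3], 10^invert_sigmoid(m, 5.5)$x)
})
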