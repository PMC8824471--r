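synthetic_trace <- function(t, current, segment = 1) {
  tibble::tibble(time_ms = t, current = current, segment = segment)
}

test_that("peak measurement returns the signed extremum and its time", {
  t <- seq(0, 20, 0.1)
  tr <- synthetic_trace(t, -2 * exp(-t / 5))
  pk <- measure_peak(tr)
  expect_equal(pk$amplitude, -2)
  expect_equal(pk$time_ms, 0)
  # monotone trace peaks at the window edge
  tr2 <- synthetic_trace(t, -t)
  expect_equal(measure_peak(tr2, c(5, 10))$time_ms, 10)
  expect_error(measure_peak(tr, c(30, 40)), "window")
})

test_that("persistent subtraction recovers transient amplitudes and is
           idempotent", {
  t <- seq(0, 50, 0.05)
  plateau <- -0.4
  tr <- synthetic_trace(t, -3 * exp(-t / 2) + plateau)
  s <- subtract_persistent(tr)
  expect_equal(attr(s, "persistent"), plateau, tolerance = 1e-6)
  expect_equal(min(s$current_sub), -3, tolerance = 1e-3)
  # constant current has zero adjusted peak
  s0 <- subtract_persistent(synthetic_trace(t, rep(-1, length(t))))
  expect_equal(max(abs(s0$current_sub)), 0, tolerance = 1e-12)
  # idempotence
  s2 <- subtract_persistent(
    synthetic_trace(t, s$current_sub))
  expect_lt(abs(min(s2$current_sub) - min(s$current_sub)), 1e-12)
  expect_warning(
    subtract_persistent(synthetic_trace(seq(0, 5, 0.1),
                                        -exp(-seq(0, 5, 0.1)))),
    "shorter than 10 ms")
})

test_that("the 1/e crossing recovers exponential time constants", {
  t <- seq(0, 60, 0.01)
  expect_equal(tau_one_over_e(t, -2 * exp(-t / 7)), 7, tolerance = 1e-4)
  # an unsubtracted offset inflates the estimate; subtraction removes it
  y <- -2 * exp(-t / 7) - 0.5
  expect_gt(tau_one_over_e(t, y), 7 * 1.2)
  expect_equal(tau_one_over_e(t, y + 0.5), 7, tolerance = 1e-4)
  expect_error(tau_one_over_e(t, -2 * exp(-t / 1e4)), "1/e")
})

test_that("single-exponential fits round-trip and match the 1/e estimate", {
  x <- seq(2, 36, 2)
  f <- fit_single_exponential(x, 2 * exp(-x / 15.5))
  expect_equal(f$tau_ms, 15.5, tolerance = 1e-6)
  expect_equal(f$amplitude, 2, tolerance = 1e-6)
  f2 <- fit_single_exponential(x, 2 * exp(-x / 15.5) + 0.3,
                               with_offset = TRUE)
  expect_equal(f2$tau_ms, 15.5, tolerance = 1e-6)
  expect_equal(f2$offset, 0.3, tolerance = 1e-6)
  # 1/e convention agrees with the fitted tau on pure exponentials
  t <- seq(0, 100, 0.01)
  tau_e <- tau_one_over_e(t, 3 * exp(-t / 12))
  tau_f <- fit_single_exponential(t[seq(1, length(t), 50)],
                                  3 * exp(-t[seq(1, length(t), 50)] / 12),
                                  with_offset = FALSE)$tau_ms
  expect_equal(tau_e, tau_f, tolerance = 0.02)
  expect_error(fit_single_exponential(x, rep(1, length(x))), "constant")
  expect_error(fit_single_exponential(1:3, c(3, 2, 1)), "4 points")
})

test_that("noisy exponential data are recovered within tolerance", {
  withr::with_seed(42, {
    x <- seq(2, 36, 2)
    y <- 1.5 * exp(-x / 15.5) + rnorm(length(x), 0, 0.02)
    f <- fit_single_exponential(x, y, with_offset = FALSE)
    expect_equal(f$tau_ms, 15.5, tolerance = 0.1)
  })
})

test_that("Boltzmann fits round-trip for rising and falling curves", {
  v <- seq(-80, 0, 5)
  up <- fit_boltzmann(v, 1 / (1 + exp((-30 - v) / 6)))
  expect_equal(up$v_half_mV, -30, tolerance = 1e-6)
  expect_equal(up$slope_mV, 6, tolerance = 1e-6)
  down <- fit_boltzmann(v, 1 / (1 + exp((-55 - v) / -5)))
  expect_equal(down$v_half_mV, -55, tolerance = 1e-6)
  expect_equal(down$slope_mV, -5, tolerance = 1e-6)
  expect_error(fit_boltzmann(v, rep(0.5, length(v))), "constant")
  expect_error(fit_boltzmann(v[1:4], c(0, 0.2, 0.8, 1)), "5 voltages")
  expect_error(fit_boltzmann(v, seq(-1, 3, length.out = length(v))),
               "normalized")
})

test_that("fit objects expose tidy and glance methods", {
  x <- seq(2, 36, 2)
  f <- fit_single_exponential(x, 2 * exp(-x / 15.5))
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(glance(f)$tau_ms, 15.5, tolerance = 1e-6)
  b <- fit_boltzmann(seq(-80, 0, 5),
                     1 / (1 + exp((-30 - seq(-80, 0, 5)) / 6)))
  expect_equal(glance(b)$v_half_mV, -30, tolerance = 1e-6)
  expect_s3_class(tidy(b), "tbl_df")
})
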