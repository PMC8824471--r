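# Protocol pipelines are deterministic simulations; tests use a 20 us
# sampling interval, which changes the measured summary values by < 0.1%
# relative to the 5 us default (see test-propagation convergence checks).

test_that("availability curve is anchored, falls to zero, and is Boltzmann-
           like over its falling limb", {
  av <- availability_curve(wt_params, control = coarse_ctl)
  expect_equal(av$y[1], 1)
  expect_lt(av$y[length(av$y)], 0.01)
  # monotone decline over the main falling limb (-70 to -10 mV); the model
  # produces a small window-current bump near -75 mV, so the full range is
  # not asserted
  limb <- av$y[av$x >= -70]
  expect_true(all(diff(limb) < 0))
  fb <- fit_boltzmann(av$x, pmin(av$y, 1.05))
  expect_lt(fb$slope_mV, 0)
  expect_lt(fb$residual_sse, 0.05)
})

test_that("activation curve is anchored at 0 mV and rises with voltage", {
  ac <- activation_curve(wt_params, control = coarse_ctl)
  expect_equal(ac$y[length(ac$y)], 1)
  # monotone rise over the steep limb; essentially saturated above -20 mV
  expect_true(all(diff(ac$y[ac$x <= -20]) > 0))
  expect_true(all(ac$y[ac$x > -20] > 0.9))
  expect_gt(min(ac$y), 0)
  fb <- fit_boltzmann(ac$x, pmin(ac$y, 1.05))
  expect_gt(fb$slope_mV, 0)
  expect_lt(fb$residual_sse, 0.05)
})

test_that("transient decay time constants are finite, positive and faster at
           stronger depolarizations", {
  ti <- inactivation_tau_curve(wt_params, control = coarse_ctl)
  expect_equal(ti$x, seq(-50, 0, 5))
  expect_true(all(is.finite(ti$y) & ti$y > 0))
  expect_lt(ti$y[length(ti$y)], ti$y[1])
})

test_that("recovery from fast inactivation is monotone and near-complete by
           20 ms", {
  rc <- recovery_curve(wt_params, control = coarse_ctl)
  expect_true(all(diff(rc$y) > -1e-6))
  expect_gt(rc$y[rc$x == 20], 0.95)
  expect_equal(rc$y[rc$x == 500], 1, tolerance = 1e-3)
})

test_that("persistent fraction is a small positive ratio", {
  pf <- persistent_fraction(wt_params, control = coarse_ctl)
  expect_gt(pf, 0)
  expect_lt(pf, 0.2)
})

test_that("resurgent-to-transient ratio peaks near -45 mV and is a proper
           fraction", {
  rr <- resurgent_ratio_curve(wt_params, control = coarse_ctl)
  expect_equal(rr$x[which.max(rr$y)], -45)
  expect_true(all(rr$y < 1))
  expect_true(all(rr$y >= 0))
  # closed-state recovery dominates at strong hyperpolarization
  expect_lt(rr$y[rr$x == -80], 0.1 * max(rr$y))
})

test_that("duration dependence is anchored and strictly decreasing with a
           convergent exponential fit", {
  dc <- duration_dependence(wt_params, control = coarse_ctl)
  expect_equal(dc$y[1], 1)
  expect_length(dc$y, 18)
  expect_true(all(diff(dc$y) < 0))
  f <- fit_single_exponential(dc$x, dc$y)
  expect_true(is.finite(f$tau_ms) && f$tau_ms > 0)
})

test_that("resurgent decay is much slower than transient decay", {
  rt <- resurgent_decay_taus(wt_params, control = coarse_ctl)
  ti <- inactivation_tau_curve(wt_params, control = coarse_ctl)
  expect_true(all(is.finite(rt$y) & rt$y > 0))
  # tens of ms, versus sub-ms transient decay
  expect_true(all(rt$y > 5))
  shared <- intersect(rt$x, ti$x)
  expect_true(all(rt$y[match(shared, rt$x)] >
                    ti$y[match(shared, ti$x)]))
})

test_that("peak resurgent current is independent of the prepulse potential", {
  ps <- prepulse_peak_spread(wt_params, control = coarse_ctl)
  expect_true(all(ps$peaks$y < 0))
  expect_lt(ps$cv, 0.02)
  # near-constant even when the prepulse range extends to +10 mV
  ps10 <- prepulse_peak_spread(wt_params, prepulse_mV = seq(-35, 10, 5),
                               control = coarse_ctl)
  expect_lt(ps10$cv, 0.05)
})

test_that("sequential recovery yields comparable transient and resurgent
           ratios in the single-population model", {
  sq <- sequential_recovery(wt_params, control = coarse_ctl)
  expect_true(all(sq$relative > 0 & sq$relative <= 1.05))
  # the model does not separate the two components' recovery: the ratios are
  # approximately equal (unlike the differential recovery seen in neurons)
  expect_lt(abs(diff(sq$relative)), 0.05)
})

test_that("the repetitive-repolarization envelope tracks the sustained trace
           initially and accumulates slow inactivation under both protocols", {
  env <- envelope_comparison(wt_params, control = coarse_ctl)
  expect_equal(env$repetitive$peak[1], env$repetitive$sustained_at[1],
               tolerance = 1e-6)
  expect_true(all(diff(env$is_occupancy$repetitive) > 0))
  expect_true(all(diff(env$is_occupancy$sustained) > 0))
  expect_true(is.finite(env$envelope_deviation))
})

test_that("ramp currents vanish at -100 mV and the two ramp directions give
           similar current-voltage relations", {
  up <- ramp_current(wt_params, "up", control = coarse_ctl)
  dn <- ramp_current(wt_params, "down", control = coarse_ctl)
  scale <- max(abs(up$y))
  expect_lt(abs(up$y[which.min(abs(up$x + 100))]), 0.05 * scale)
  grid <- seq(-95, -5, 5)
  ui <- approx(up$x, up$y, xout = grid)$y
  di <- approx(dn$x, dn$y, xout = grid)$y
  expect_lt(max(abs(ui - di)) / scale, 0.25)
  # the up-ramp current-voltage relation is the quasi-steady persistent
  # (window) component: it peaks at intermediate voltages and fades toward
  # both ends
  vpk <- up$x[which.min(up$y)]
  expect_true(vpk > -80 && vpk < -40)
  expect_lt(abs(up$y[length(up$y)]), 0.1 * scale)
})

test_that("protocol outputs are reproducible run-to-run", {
  a <- duration_dependence(wt_params, control = coarse_ctl)
  b <- duration_dependence(wt_params, control = coarse_ctl)
  expect_identical(a$y, b$y)
  expect_identical(run_protocol(wt_model, "availability", coarse_ctl)$y,
                   run_protocol(wt_model, "availability", coarse_ctl)$y)
})

test_that("run_protocol rejects unknown ids", {
  expect_error(run_protocol(wt_model, "nope"), "unknown protocol")
})
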