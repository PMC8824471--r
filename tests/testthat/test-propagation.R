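test_that("Nernst potentials match the standard recording conditions", {
  expect_equal(nernst_potential(151, 8, 295), 74.683, tolerance = 1e-3)
  expect_equal(nernst_potential(50, 15, 295), 30.606, tolerance = 1e-3)
  expect_equal(nernst_potential(10, 10, 295), 0)
  expect_error(nernst_potential(-1, 8), "> 0")
  expect_error(nernst_potential(151, 0), "> 0")
})

test_that("steady state solves p Q = 0 and matches long-horizon propagation", {
  for (V in c(-120, -90, -45, 0)) {
    p <- steady_state(wt_model, V)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    Q <- build_generator(wt_params, V)
    expect_lt(max(abs(p %*% Q)), 1e-9)
  }
  # long propagation from an arbitrary start reaches the same distribution
  p0 <- setNames(rep(1 / 9, 9), nav_scheme()$states)
  for (V in c(-90, -45)) {
    # scaling-squaring over such a long horizon accumulates a ~1e-7
    # conservation drift, which propagate() renormalizes with a warning
    p_long <- suppressWarnings(propagate(p0, wt_model, V, 1e5))
    expect_equal(unname(p_long), unname(steady_state(wt_model, V)),
                 tolerance = 1e-8)
  }
})

test_that("sustained depolarization drives occupancy into the slow-inactivated
           state", {
  p <- steady_state(wt_model, 0)
  expect_lt(p[["O"]], 1e-3)
  expect_gt(p[["IS"]], 0.9)
})

test_that("propagation is the identity at dt = 0 and a semigroup at fixed
           voltage", {
  p <- steady_state(wt_model, -90)
  expect_identical(propagate(p, wt_model, -45, 0), p)
  p1 <- propagate(propagate(p, wt_model, -45, 0.5), wt_model, -45, 0.5)
  p2 <- propagate(p, wt_model, -45, 1)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("matrix-exponential propagation agrees with fine-step explicit
           integration", {
  p0 <- post_depol_state()
  # explicit Euler oracle at the -45 mV segment
  p_euler <- euler_propagate(wt_model, p0, -45, 5, dt = 1e-4)
  p_expm <- propagate(p0, wt_model, -45, 5)
  expect_lt(max(abs(p_expm - p_euler)), 1e-6)
  # RK4 oracle at a depolarized (stiffer) segment
  p_rk4 <- rk4_propagate(wt_model, steady_state(wt_model, -90), 0, 2,
                         dt = 1e-4)
  p_expm2 <- propagate(steady_state(wt_model, -90), wt_model, 0, 2)
  expect_lt(max(abs(p_expm2 - p_rk4)), 1e-6)
})

test_that("simulated traces conserve probability and stay at rest when held", {
  pr <- vc_protocol(-90, sample_interval_ms = 0.05) |> vc_step(-90, 50)
  tr <- simulate_nav(wt_model, pr)
  occ <- as.matrix(tr[, nav_scheme()$states])
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  p0 <- steady_state(wt_model, -90)
  expect_lt(max(abs(sweep(occ, 2, p0))), 1e-9)
})

test_that("the classic two-step paradigm shows the three current components", {
  pr <- vc_protocol(-90, sample_interval_ms = 0.01) |>
    vc_step(0, 5) |> vc_step(-45, 100)
  tr <- simulate_nav(wt_model, pr)
  # inward current whenever open below the reversal potential
  expect_true(all(tr$current[tr$open_prob > 0 & tr$voltage_mV < 75] <= 0))
  s1 <- tr[tr$segment == 1, ]
  s2 <- subtract_persistent(tr, segment = 2)
  pk1 <- measure_peak(s1)
  # transient: peaks early within the depolarizing step, then decays
  expect_lt(pk1$time_ms, 1)
  expect_gt(abs(pk1$amplitude), abs(s1$current[nrow(s1)]) * 2)
  # resurgent: rises after the segment onset (peak strictly later) and is
  # much slower than the transient
  k <- which.min(s2$current_sub)
  t_on <- min(s2$time_ms)
  expect_gt(s2$time_ms[k] - t_on, 10 * pk1$time_ms)
  # persistent plateau: nonzero inward at the end of the long step
  expect_lt(attr(s2, "persistent"), 0)
})

test_that("peak measurements are converged in the sampling interval", {
  peak_at <- function(dt) {
    pr <- vc_protocol(-90, sample_interval_ms = dt) |>
      vc_step(0, 5) |> vc_step(-45, 100)
    tr <- simulate_nav(wt_model, pr)
    c(min(tr$current[tr$segment == 1]),
      min(subtract_persistent(tr, segment = 2)$current_sub))
  }
  expect_equal(peak_at(0.005), peak_at(0.0025), tolerance = 1e-3)
})

test_that("ramp discretization is converged", {
  up1 <- ramp_current(wt_model, "up",
                      control = protocol_control(ramp_dV = 0.25))
  up2 <- ramp_current(wt_model, "up",
                      control = protocol_control(ramp_dV = 0.125))
  pk1 <- min(up1$y)
  pk2 <- min(approx(up2$x, up2$y, xout = up1$x)$y, na.rm = TRUE)
  expect_equal(pk1, pk2, tolerance = 5e-3)
})

test_that("protocol builders validate their inputs", {
  expect_error(vc_step(vc_protocol(-90), 0, -5), "duration")
  expect_error(vc_ramp(vc_protocol(-90), to_mV = 0, slope_mV_per_ms = -0.12),
               "slope")
  expect_error(simulate_nav(wt_model, vc_protocol(-90)), "no segments")
})
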