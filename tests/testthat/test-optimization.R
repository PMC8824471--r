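# Fitting machinery. Target synthesis and cost tests run at a 50 us sampling
# interval; recovery experiments use protocol weights to keep runtimes
# proportionate (the full nine-protocol, three-seed recovery experiment runs
# in the acceptance suite).

fit_ctl <- protocol_control(sample_interval_ms = 0.05)

test_that("self-generated noiseless targets have zero cost at the generating
           parameters", {
  targets <- synthesize_targets(wt_params, noise_sd = 0, control = fit_ctl)
  expect_lt(total_cost(wt_params, targets), 1e-12)
  for (id in c("duration", "activation", "inar_ratio")) {
    expect_lt(protocol_cost(wt_params, id, targets$curves[[id]], fit_ctl),
              1e-12)
  }
})

test_that("cost arithmetic: uniform shifts, weights and grid mismatches", {
  targets <- synthesize_targets(wt_params, noise_sd = 0, control = fit_ctl)
  tgt <- targets$curves$duration
  tgt$y <- tgt$y + 0.1
  expect_equal(protocol_cost(wt_params, "duration", tgt, fit_ctl),
               0.01 * nrow(tgt), tolerance = 1e-9)
  # zero weights null the total cost
  targets0 <- targets
  targets0$weights[] <- 0
  expect_identical(total_cost(ko_params, targets0), 0)
  # total equals the sum of per-protocol costs at unit weights
  per <- vapply(names(targets$curves), function(id) {
    protocol_cost(ko_params, id, targets$curves[[id]], fit_ctl)
  }, numeric(1))
  expect_equal(total_cost(ko_params, targets), sum(per), tolerance = 1e-9)
  expect_gt(per[["inar_ratio"]], 0)  # the two printed variants differ
  bad <- tgt[-1, ]
  expect_error(protocol_cost(wt_params, "duration", bad, fit_ctl), "grid")
})

test_that("the prepulse protocol admits the dispersion cost form", {
  disp <- protocol_cost(wt_params, "prepulse", NULL, fit_ctl)
  expect_gte(disp, 0)
  expect_lt(disp, 0.05)  # the optimized model has near-constant peaks
  expect_error(protocol_cost(wt_params, "duration", NULL, fit_ctl),
               "prepulse")
})

test_that("the simplex minimizer matches an independent Nelder-Mead on a
           smooth test function", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  ours <- resurgenav:::nelder_mead(rosen, c(-1.2, 1), tol_cost = 1e-10,
                                   tol_par = 1e-6, max_evals = 5000,
                                   init_step = 0.5)
  ref <- optim(c(-1.2, 1), rosen, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(ours$par, c(1, 1), tolerance = 1e-3)
  expect_equal(ours$value, ref$value, tolerance = 1e-4)
  expect_true(ours$converged)
  # monotone progress of the best vertex
  expect_true(all(diff(ours$trace) <= 1e-12))
})

test_that("target synthesis is reproducible and noise-free targets equal the
           direct protocol outputs", {
  t1 <- synthesize_targets(wt_params, noise_sd = 0.02, seed = 7,
                           control = fit_ctl)
  t2 <- synthesize_targets(wt_params, noise_sd = 0.02, seed = 7,
                           control = fit_ctl)
  expect_identical(t1$curves$duration$y, t2$curves$duration$y)
  t3 <- synthesize_targets(wt_params, noise_sd = 0.02, seed = 8,
                           control = fit_ctl)
  expect_false(identical(t1$curves$duration$y, t3$curves$duration$y))
  t0 <- synthesize_targets(wt_params, noise_sd = 0, control = fit_ctl)
  direct <- duration_dependence(wt_params, control = fit_ctl)
  expect_identical(t0$curves$duration$y, direct$y)
})

test_that("non-positive rate parameters are rejected before any simulation", {
  v <- wt_params$values
  v[["a2_variable1"]] <- 0
  expect_error(new_nav_params(v), "positive")
  expect_error(fit_parameters(list(values = v), NULL), "nav_params")
})

test_that("a perturbed start is pulled back to the target curves", {
  # two-protocol recovery (duration + inar_ratio carry the resurgent
  # phenotype); the full nine-protocol experiment runs in the acceptance
  # suite
  targets <- synthesize_targets(
    wt_params, noise_sd = 0, control = fit_ctl,
    weights = c(availability = 0, activation = 0, tau_inact = 0,
                recovery = 0, persistent = 0, inar_tau = 0, prepulse = 0))
  set.seed(5)
  idx <- sample(24, 3)
  v <- wt_params$values
  v[idx] <- v[idx] * 1.3
  pert <- new_nav_params(v, label = "perturbed")
  f0 <- total_cost(pert, targets)
  expect_gt(f0, 0)
  fit <- fit_parameters(pert, targets, max_evals = 400, tol_cost = 1e-8,
                        tol_par = 1e-4)
  expect_lte(fit$final_cost, fit$initial_cost)
  expect_lt(fit$final_cost, f0 / 50)
  expect_true(all(fit$params$values > 0))
  # curve-space recovery on the weighted protocols
  for (id in c("duration", "inar_ratio")) {
    sim <- run_protocol(nav_model(fit$params), id, fit_ctl)
    expect_lt(max(abs(sim$y - targets$curves[[id]]$y)) /
                max(abs(targets$curves[[id]]$y)), 0.05)
  }
  # best-cost trace is non-increasing
  expect_true(all(diff(fit$cost_trace) <= 1e-12))
})

test_that("refitting from the wild-type start against its own curves stays at
           the wild type", {
  wt_curve <- resurgent_ratio_curve(wt_params, control = fit_ctl)
  fit <- refit_scn4b(wt_params, wt_curve, control = fit_ctl, max_evals = 30)
  expect_lt(fit$final_cost, 1e-12)
  expect_equal(fit$params$values, wt_params$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the shipped Scn4b-null parameters shift occupancy from fast- to
           slow-inactivated states", {
  # during a 5 ms depolarization to 0 mV from rest, the Navbeta4-null model
  # accumulates less IF2 and more IS than wild type
  occ_at <- function(params) {
    p <- steady_state(nav_model(params), -90)
    propagate(p, nav_model(params), 0, 5)
  }
  wt_occ <- occ_at(wt_params)
  ko_occ <- occ_at(ko_params)
  expect_lt(ko_occ[["IF2"]], wt_occ[["IF2"]])
  expect_gt(ko_occ[["IS"]], wt_occ[["IS"]])
})

test_that("fit objects expose tidy and glance methods", {
  targets <- synthesize_targets(
    wt_params, noise_sd = 0, control = fit_ctl,
    weights = setNames(rep(0, 9), names(targets_ids <- c(
      "availability", "activation", "tau_inact", "recovery", "persistent",
      "inar_ratio", "duration", "inar_tau", "prepulse"))))
  fit <- fit_parameters(wt_params, targets, max_evals = 26)
  expect_named(glance(fit),
               c("initial_cost", "final_cost", "evals", "converged"))
  expect_equal(nrow(tidy(fit)), 24)
})
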