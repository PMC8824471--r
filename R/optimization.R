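#' Synthesize fitting targets from a parameter set
#'
#' Runs all nine optimization protocols under `params` and adds independent
#' Gaussian noise to every y value, producing a reproducible target set for
#' parameter-recovery experiments. This stands in for experimental mean
#' curves, which are available only as figures.
#'
#' @param params A `nav_params` object.
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Integer seed (fixed noise realization).
#' @param control A [protocol_control()]; the same control should be used
#'   when fitting against the targets.
#' @param weights Named per-protocol weights (default 1).
#'
#' @return An object of class `nav_targets`: list of `nav_curve`s keyed by
#'   protocol id, plus `weights` and the generating `control`.
#' @export
synthesize_targets <- function(params, noise_sd = 0, seed = 1,
                               control = protocol_control(),
                               weights = NULL) {
  stopifnot(noise_sd >= 0)
  model <- as_nav_model(params)
  ids <- names(protocol_registry())
  curves <- lapply(ids, function(id) run_protocol(model, id, control))
  names(curves) <- ids
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    for (id in ids) {
      curves[[id]]$y <- curves[[id]]$y + rnorm(nrow(curves[[id]]), 0, noise_sd)
    }
  }
  w <- setNames(rep(1, length(ids)), ids)
  if (!is.null(weights)) w[names(weights)] <- weights
  structure(list(curves = curves, weights = w, control = control,
                 noise_sd = noise_sd, seed = seed),
            class = "nav_targets")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cost of one protocol against a target curve
#'
#' Sum of squared differences between the simulated and target y values on
#' the protocol's x grid. For the `prepulse` protocol with `target = NULL`,
#' the cost is the dispersion of the simulated peaks around their mean (the
#' published optimization goal: the peak resurgent current should be constant
#' across prepulse potentials, without fixing its magnitude a priori).
#'
#' @param params A `nav_params`.
#' @param id Protocol id.
#' @param target A `nav_curve` (or NULL for the prepulse dispersion form).
#' @param control A [protocol_control()].
#'
#' @return Non-negative scalar.
#' @export
protocol_cost <- function(params, id, target, control = protocol_control()) {
  sim <- run_protocol(as_nav_model(params), id, control)
  if (is.null(target)) {
    if (id != "prepulse") abort("only `prepulse` admits a NULL target")
    return(sum((sim$y - mean(sim$y))^2))
  }
  if (nrow(sim) != nrow(target) || max(abs(sim$x - target$x)) > 1e-9) {
    abort(paste0("target x grid does not match the '", id,
                 "' protocol definition"))
  }
  sum((sim$y - target$y)^2)
}

#' Total cost over a target set
#'
#' Weighted sum of [protocol_cost()] over all protocols in the target set.
#'
#' @param params A `nav_params`.
#' @param targets A `nav_targets` object.
#'
#' @return Non-negative scalar.
#' @export
total_cost <- function(params, targets) {
  stopifnot(inherits(targets, "nav_targets"))
  model <- as_nav_model(params)
  ids <- names(targets$curves)
  sum(vapply(ids, function(id) {
    w <- targets$weights[[id]]
    if (w == 0) return(0)
    w * protocol_cost(model, id, targets$curves[[id]], targets$control)
  }, numeric(1)))
}

# ---- Nelder-Mead simplex (log-parameter space) -----------------------------

# Standard Nelder-Mead with the Lagarias et al. coefficients; termination
# follows the published convention: absolute spread of the simplex costs and
# of the (log) parameters both below their tolerances. Positivity of rate
# constants is guaranteed by optimizing log-parameters.
nelder_mead <- function(fn, x0, tol_cost = 0.01, tol_par = 0.01,
                        max_evals = 5000, init_step = 0.05) {
  n <- length(x0)
  evals <- 0L
  trace_best <- numeric(0)
  f <- function(x) {
    evals <<- evals + 1L
    fn(x)
  }
  simplex <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) simplex[i + 1, i] <- simplex[i + 1, i] + init_step
  fv <- apply(simplex, 1, f)
  converged <- FALSE
  repeat {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]
    fv <- fv[ord]
    trace_best <- c(trace_best, fv[1])
    if (max(abs(fv[-1] - fv[1])) <= tol_cost &&
        max(abs(sweep(simplex[-1, , drop = FALSE], 2, simplex[1, ]))) <=
        tol_par) {
      converged <- TRUE
      break
    }
    if (evals >= max_evals) break
    centroid <- colMeans(simplex[-(n + 1), , drop = FALSE])
    xr <- centroid + (centroid - simplex[n + 1, ])
    fr <- f(xr)
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - simplex[n + 1, ])
      fe <- f(xe)
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      if (fr < fv[n + 1]) {
        xc <- centroid + 0.5 * (xr - centroid)
        fc <- f(xc)
        shrink <- fc >= fr
        if (!shrink) { simplex[n + 1, ] <- xc; fv[n + 1] <- fc }
      } else {
        xc <- centroid - 0.5 * (centroid - simplex[n + 1, ])
        fc <- f(xc)
        shrink <- fc >= fv[n + 1]
        if (!shrink) { simplex[n + 1, ] <- xc; fv[n + 1] <- fc }
      }
      if (shrink) {
        for (i in 2:(n + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- f(simplex[i, ])
        }
      }
    }
  }
  ord <- order(fv)
  list(par = simplex[ord[1], ], value = fv[ord[1]], evals = evals,
       converged = converged, trace = trace_best)
}

#' Fit the 24 rate parameters to a target set
#'
#' Constrained Nelder-Mead minimization of [total_cost()] starting from
#' `initial`. Positivity of the rate constants is enforced by optimizing in
#' log-parameter space. Convergence follows the published tolerances: 0.01
#' for the change of the cost function and 0.01 for the change in (log)
#' parameters; hitting the evaluation cap returns `converged = FALSE` rather
#' than an error.
#'
#' @param initial A `nav_params` starting point (all parameters > 0).
#' @param targets A `nav_targets`.
#' @param tol_cost,tol_par Convergence tolerances.
#' @param max_evals Cap on cost evaluations.
#' @param init_step Initial simplex displacement in log space.
#'
#' @return A list of class `nav_fit`: `params` (fitted `nav_params`),
#'   `initial_cost`, `final_cost`, `per_protocol_costs`, `evals`,
#'   `converged`, `cost_trace`.
#' @export
fit_parameters <- function(initial, targets, tol_cost = 0.01, tol_par = 0.01,
                           max_evals = 5000, init_step = 0.05) {
  stopifnot(inherits(initial, "nav_params"), inherits(targets, "nav_targets"))
  if (any(initial$values <= 0)) abort("initial parameters must be positive")
  nm <- nav_param_names()
  mk <- function(logx) {
    new_nav_params(setNames(exp(logx), nm), q10 = initial$q10,
                   temperature_K = initial$temperature_K,
                   label = paste0(initial$label, " (fit)"))
  }
  fn <- function(logx) {
    tryCatch(total_cost(mk(logx), targets), error = function(e) Inf)
  }
  x0 <- log(initial$values)
  f0 <- fn(x0)
  res <- nelder_mead(fn, x0, tol_cost = tol_cost, tol_par = tol_par,
                     max_evals = max_evals, init_step = init_step)
  best <- if (res$value <= f0) res$par else x0
  fitted <- mk(best)
  per <- vapply(names(targets$curves), function(id) {
    protocol_cost(fitted, id, targets$curves[[id]], targets$control)
  }, numeric(1))
  structure(
    list(params = fitted, initial_cost = f0,
         final_cost = min(res$value, f0),
         per_protocol_costs = per, evals = res$evals,
         converged = res$converged, cost_trace = res$trace),
    class = "nav_fit")
}

#' @export
print.nav_fit <- function(x, ...) {
  cat("<nav_fit> cost ", format(x$initial_cost, digits = 5), " -> ",
      format(x$final_cost, digits = 5), " in ", x$evals,
      " evaluations (converged: ", x$converged, ")\n", sep = "")
  invisible(x)
}

#' @method tidy nav_fit
#' @export
tidy.nav_fit <- function(x, ...) {
  tibble(parameter = names(x$params$values),
         estimate = unname(x$params$values))
}

#' @method glance nav_fit
#' @export
glance.nav_fit <- function(x, ...) {
  tibble(initial_cost = x$initial_cost, final_cost = x$final_cost,
         evals = x$evals, converged = x$converged)
}

#' Refit for the Scn4b-null variant
#'
#' Restarts the optimization from the wild-type rate constants with the
#' resurgent-to-transient ratio protocol (`inar_ratio`) targeting a supplied
#' (reduced-amplitude) curve while all other protocols keep the wild-type
#' model's own curves as targets, so that only the resurgent amplitude is
#' pushed down.
#'
#' @param wt_params Wild-type `nav_params` (the starting point and the source
#'   of the unchanged targets).
#' @param scn4b_ratio_target A `nav_curve` on the `inar_ratio` grid.
#' @inheritParams fit_parameters
#' @param control A [protocol_control()].
#'
#' @return A `nav_fit`.
#' @export
refit_scn4b <- function(wt_params, scn4b_ratio_target,
                        control = protocol_control(), ...) {
  targets <- synthesize_targets(wt_params, noise_sd = 0, control = control)
  if (nrow(scn4b_ratio_target) != nrow(targets$curves$inar_ratio)) {
    abort("`scn4b_ratio_target` grid does not match the inar_ratio protocol")
  }
  targets$curves$inar_ratio$y <- scn4b_ratio_target$y
  fit_parameters(wt_params, targets, ...)
}
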