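#' Peak current in a time window
#'
#' Returns the extremum of the current (largest absolute value, sign
#' preserved) inside a window of a simulated trace, and the time at which it
#' occurs.
#'
#' @param trace A `nav_trace` (or any data frame with `time_ms` and
#'   `current`).
#' @param window Numeric length-2 `c(t0, t1)` in ms; defaults to the whole
#'   trace.
#'
#' @return A one-row tibble with `amplitude` and `time_ms`.
#' @export
measure_peak <- function(trace, window = NULL) {
  tt <- trace$time_ms
  ii <- trace$current
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    if (!any(keep)) abort("empty measurement window")
    tt <- tt[keep]; ii <- ii[keep]
  }
  k <- which.max(abs(ii))
  tibble(amplitude = ii[k], time_ms = tt[k])
}

# Persistent (quasi-steady) level of a current vector: mean of the final
# fraction of the samples.
persistent_level <- function(current, frac = 0.05) {
  n <- length(current)
  mean(current[max(1, n - max(2, round(frac * n)) + 1):n])
}

#' Subtract the persistent current component
#'
#' Implements the standard measurement convention: the non-inactivating
#' (persistent) level, estimated as the mean over the final 5% of the
#' segment, is subtracted from the current before peaks or decay constants
#' are measured. Subtraction is idempotent.
#'
#' @param trace A `nav_trace` or data frame with `time_ms` and `current`.
#' @param segment Optional segment id to restrict to (uses the `segment`
#'   column).
#' @param frac Trailing fraction of samples used for the persistent estimate.
#'
#' @return The input rows (restricted to `segment` if given) with an added
#'   column `current_sub` and attribute `persistent` (the subtracted level).
#' @export
subtract_persistent <- function(trace, segment = NULL, frac = 0.05) {
  x <- trace
  if (!is.null(segment)) x <- x[x$segment == segment, , drop = FALSE]
  if (nrow(x) < 2) abort("segment too short to estimate a persistent level")
  dur <- max(x$time_ms) - min(x$time_ms)
  if (dur < 10) {
    warn("segment shorter than 10 ms: persistent level may be unreliable")
  }
  lev <- persistent_level(x$current, frac)
  x$current_sub <- x$current - lev
  attr(x, "persistent") <- lev
  x
}

#' 1/e decay time constant
#'
#' The time after the peak at which the (persistent-subtracted) current first
#' falls to `1/e` of its peak magnitude. The published description calls this
#' "64% decay"; 1/e retention is 63.2% decay, and the exact crossing is used,
#' with linear interpolation between samples.
#'
#' @param time_ms,current Numeric vectors (one decay segment, already
#'   persistent-subtracted if required).
#' @param peak_time Optional time of the peak; defaults to the extremum of
#'   `|current|`.
#'
#' @return Decay time constant in ms.
#' @export
tau_one_over_e <- function(time_ms, current, peak_time = NULL) {
  if (is.null(peak_time)) {
    k <- which.max(abs(current))
  } else {
    k <- which.min(abs(time_ms - peak_time))
  }
  target <- abs(current[k]) / exp(1)
  mag <- abs(current[k:length(current)])
  tt <- time_ms[k:length(current)]
  below <- which(mag <= target)
  if (!length(below)) {
    abort("decay does not reach 1/e of the peak within the segment")
  }
  j <- below[1]
  if (j == 1) return(0)
  # linear interpolation of the crossing
  t_cross <- tt[j - 1] + (tt[j] - tt[j - 1]) *
    (mag[j - 1] - target) / (mag[j - 1] - mag[j])
  t_cross - time_ms[k]
}

#' Fit a single exponential decay
#'
#' Least-squares fit of `y = A * exp(-x / tau)` (plus an offset `C` if
#' `with_offset`), with the deterministic initialization `A = y[1] - C`,
#' `C = y[n]` (0 when offset-free), `tau = range(x) / 3`.
#'
#' @param x,y Numeric vectors (>= 4 points; `y` must not be constant).
#' @param with_offset Include an additive offset term.
#'
#' @return An object of class `nav_exp_fit` with elements `amplitude`,
#'   `tau_ms`, `offset`, `residual_sse`, `fitted`, `data`. Supports [tidy()]
#'   and [glance()].
#' @examples
#' x <- seq(2, 36, 2)
#' fit <- fit_single_exponential(x, 2 * exp(-x / 15.5))
#' tidy(fit)
#' @export
fit_single_exponential <- function(x, y, with_offset = TRUE) {
  if (length(x) < 4) abort("need at least 4 points")
  if (length(x) != length(y)) abort("`x` and `y` lengths differ")
  if (sd(y) == 0) abort("`y` is constant; nothing to fit")
  tau0 <- diff(range(x)) / 3
  dat <- tibble(x = x, y = y)
  fit <- tryCatch({
    if (with_offset) {
      minpack.lm::nlsLM(
        y ~ A * exp(-x / tau) + C, data = dat,
        start = list(A = y[1] - y[length(y)], tau = tau0, C = y[length(y)]),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ A * exp(-x / tau), data = dat,
        start = list(A = y[1], tau = tau0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(paste0("single-exponential fit failed (initial tau = ",
                 format(tau0), "): ", conditionMessage(e)))
  })
  cf <- coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    abort("single-exponential fit returned a non-positive tau")
  }
  structure(
    list(amplitude = unname(cf[["A"]]), tau_ms = unname(cf[["tau"]]),
         offset = if (with_offset) unname(cf[["C"]]) else 0,
         residual_sse = sum(stats::residuals(fit)^2),
         fitted = stats::fitted(fit), data = dat,
         with_offset = with_offset),
    class = "nav_exp_fit")
}

#' @export
print.nav_exp_fit <- function(x, ...) {
  cat("<nav_exp_fit> A =", signif(x$amplitude, 5), " tau =",
      signif(x$tau_ms, 5), "ms  C =", signif(x$offset, 5),
      " SSE =", format(x$residual_sse, digits = 4), "\n")
  invisible(x)
}

#' @method tidy nav_exp_fit
#' @export
tidy.nav_exp_fit <- function(x, ...) {
  tibble(term = c("amplitude", "tau_ms", "offset"),
         estimate = c(x$amplitude, x$tau_ms, x$offset))
}

#' @method glance nav_exp_fit
#' @export
glance.nav_exp_fit <- function(x, ...) {
  tibble(tau_ms = x$tau_ms, residual_sse = x$residual_sse,
         n = nrow(x$data), with_offset = x$with_offset)
}

#' Fit a Boltzmann function
#'
#' Least-squares fit of `y = 1 / (1 + exp((V_half - V) / k))`. A positive
#' slope factor `k` describes a curve rising with voltage (activation), a
#' negative one a falling curve (availability / steady-state inactivation).
#'
#' @param voltage_mV,y Numeric vectors (>= 5 voltages; `y` roughly in
#'   `[0, 1.05]`).
#'
#' @return An object of class `nav_boltzmann_fit` with `v_half_mV`,
#'   `slope_mV`, `residual_sse`, `fitted`, `data`. Supports [tidy()] /
#'   [glance()].
#' @examples
#' v <- seq(-80, 0, 5)
#' fit <- fit_boltzmann(v, 1 / (1 + exp((-30 - v) / 6)))
#' glance(fit)
#' @export
fit_boltzmann <- function(voltage_mV, y) {
  if (length(voltage_mV) < 5) abort("need at least 5 voltages")
  if (length(voltage_mV) != length(y)) abort("length mismatch")
  if (min(y) < -0.05 || max(y) > 1.05) {
    abort("`y` must be normalized (within [0, 1.05])")
  }
  if (sd(y) == 0) abort("`y` is constant; nothing to fit")
  rising <- y[which.max(voltage_mV)] >= y[which.min(voltage_mV)]
  v0 <- voltage_mV[which.min(abs(y - 0.5))]
  dat <- tibble(V = voltage_mV, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + exp((vh - V) / k)), data = dat,
      start = list(vh = v0, k = if (rising) 6 else -6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("Boltzmann fit failed: ", conditionMessage(e)))
    })
  cf <- coef(fit)
  if (cf[["k"]] == 0) abort("Boltzmann fit returned a zero slope")
  structure(
    list(v_half_mV = unname(cf[["vh"]]), slope_mV = unname(cf[["k"]]),
         residual_sse = sum(stats::residuals(fit)^2),
         fitted = stats::fitted(fit), data = dat),
    class = "nav_boltzmann_fit")
}

#' @export
print.nav_boltzmann_fit <- function(x, ...) {
  cat("<nav_boltzmann_fit> V1/2 =", signif(x$v_half_mV, 5), "mV  k =",
      signif(x$slope_mV, 5), "mV  SSE =",
      format(x$residual_sse, digits = 4), "\n")
  invisible(x)
}

#' @method tidy nav_boltzmann_fit
#' @export
tidy.nav_boltzmann_fit <- function(x, ...) {
  tibble(term = c("v_half_mV", "slope_mV"),
         estimate = c(x$v_half_mV, x$slope_mV))
}

#' @method glance nav_boltzmann_fit
#' @export
glance.nav_boltzmann_fit <- function(x, ...) {
  tibble(v_half_mV = x$v_half_mV, slope_mV = x$slope_mV,
         residual_sse = x$residual_sse, n = nrow(x$data))
}
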