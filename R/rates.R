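#' Evaluate the sixteen transition rates at a membrane potential
#'
#' Computes every transition rate of the nine-state gating scheme from a
#' parameter set, at one or more membrane potentials. Fourteen rates follow
#' the published single-exponential voltage dependences (scaled by the Q10
#' temperature factor); the remaining two, `b2` (IF1 -> O) and `b3s`
#' (C3 -> IS), are never free: they are derived from microscopic
#' reversibility around the C3-O-IF1 and C3-O-IS cycles,
#' `b2 = (a13 * a2 * a3) / (b13 * b3)` and
#' `b3s = (a2s * a3s * a13) / (b2s * b13)`.
#'
#' @param params A `nav_params` object.
#' @param voltage_mV Membrane potential(s) in mV. Values outside roughly
#'   +/- 500 mV overflow the exponentials and raise an error.
#'
#' @return A tibble with one row per voltage: column `voltage_mV` followed by
#'   the sixteen rates (1/ms): `a11, a12, a13, b11, b12, b13, a2, b2, a3, b3,
#'   a6, b6, a2s, b2s, a3s, b3s`.
#' @examples
#' evaluate_rates(nav_parameters("WT"), c(-90, -45, 0))
#' @export
evaluate_rates <- function(params, voltage_mV) {
  stopifnot(inherits(params, "nav_params"))
  if (!all(is.finite(voltage_mV))) abort("`voltage_mV` must be finite")
  if (any(abs(voltage_mV) > 500)) {
    abort("`voltage_mV` out of range: rate equations overflow beyond ~500 mV")
  }
  p <- params$values
  tf <- temperature_factor(params$q10, params$temperature_K)
  V <- voltage_mV
  out <- eval_rates_tibble(p, tf, V)
  if (!all(is.finite(as.matrix(out[-1])))) {
    abort("non-finite transition rate (overflow); check voltage and parameters")
  }
  out
}

nav_rate_names <- c("a11", "a12", "a13", "b11", "b12", "b13", "a2", "b2",
                    "a3", "b3", "a6", "b6", "a2s", "b2s", "a3s", "b3s")

# Fast numeric path: the sixteen rates at a single voltage, no tibble.
eval_rates_num <- function(params, V) {
  p <- params$values
  tf <- temperature_factor(params$q10, params$temperature_K)
  a11 <- tf / (p[[1]] * exp(-V / p[[2]]))
  b11 <- tf / (p[[5]] * exp(V / p[[6]]))
  a12 <- p[[3]] * a11
  a13 <- p[[4]] * a11
  b12 <- p[[7]] * b11
  b13 <- p[[8]] * b11
  a3 <- tf * p[[9]] * exp(-V / p[[10]])
  b3 <- tf * p[[11]] * exp(V / p[[12]])
  a2 <- tf * p[[13]] * exp(V / p[[14]])
  a6 <- tf * p[[15]] * exp(V / p[[16]])
  b6 <- tf * p[[17]] * exp(-V / p[[18]])
  a2s <- tf * p[[19]] * exp(V / p[[20]])
  b2s <- tf * p[[21]] * exp(-V / p[[22]])
  a3s <- tf * p[[23]] * exp(-V / p[[24]])
  b2 <- (a13 * a2 * a3) / (b13 * b3)
  b3s <- (a2s * a3s * a13) / (b2s * b13)
  c(a11 = a11, a12 = a12, a13 = a13, b11 = b11, b12 = b12, b13 = b13,
    a2 = a2, b2 = b2, a3 = a3, b3 = b3, a6 = a6, b6 = b6,
    a2s = a2s, b2s = b2s, a3s = a3s, b3s = b3s)
}

eval_rates_tibble <- function(p, tf, V) {

  a11 <- tf / (p[["a11_variable1"]] * exp(-V / p[["a11_variable2"]]))
  b11 <- tf / (p[["b11_variable1"]] * exp(V / p[["b11_variable2"]]))
  a12 <- p[["a12"]] * a11
  a13 <- p[["a13"]] * a11
  b12 <- p[["b12"]] * b11
  b13 <- p[["b13"]] * b11
  a3 <- tf * p[["a3_variable1"]] * exp(-V / p[["a3_variable2"]])
  b3 <- tf * p[["b3_variable1"]] * exp(V / p[["b3_variable2"]])
  a2 <- tf * p[["a2_variable1"]] * exp(V / p[["a2_variable2"]])
  a6 <- tf * p[["a6_variable1"]] * exp(V / p[["a6_variable2"]])
  b6 <- tf * p[["b6_variable1"]] * exp(-V / p[["b6_variable2"]])
  a2s <- tf * p[["a2s_variable1"]] * exp(V / p[["a2s_variable2"]])
  b2s <- tf * p[["b2s_variable1"]] * exp(-V / p[["b2s_variable2"]])
  a3s <- tf * p[["a3s_variable1"]] * exp(-V / p[["a3s_variable2"]])
  # microscopic reversibility: the two derived rates
  b2 <- (a13 * a2 * a3) / (b13 * b3)
  b3s <- (a2s * a3s * a13) / (b2s * b13)

  tibble(
    voltage_mV = V,
    a11 = a11, a12 = a12, a13 = a13, b11 = b11, b12 = b12, b13 = b13,
    a2 = a2, b2 = b2, a3 = a3, b3 = b3, a6 = a6, b6 = b6,
    a2s = a2s, b2s = b2s, a3s = a3s, b3s = b3s)
}

#' Microscopic-reversibility cycle residuals
#'
#' For each voltage, evaluates the imbalance of the two constrained cycles:
#' `residual_fast = a13*a2*a3 - b13*b2*b3` (C3-O-IF1) and
#' `residual_slow = a13*a2s*a3s - b13*b2s*b3s` (C3-O-IS). Both vanish (to
#' rounding) when `b2`/`b3s` come from [evaluate_rates()].
#'
#' @inheritParams evaluate_rates
#' @param rates Optional tibble of rates (one row per voltage) to check
#'   instead of rates evaluated from `params`; must carry the same columns as
#'   the output of [evaluate_rates()].
#'
#' @return A tibble with columns `voltage_mV`, `residual_fast`,
#'   `residual_slow`.
#' @export
cycle_balance_residuals <- function(params, voltage_mV, rates = NULL) {
  r <- if (is.null(rates)) evaluate_rates(params, voltage_mV) else rates
  tibble(
    voltage_mV = r$voltage_mV,
    residual_fast = r$a13 * r$a2 * r$a3 - r$b13 * r$b2 * r$b3,
    residual_slow = r$a13 * r$a2s * r$a3s - r$b13 * r$b2s * r$b3s)
}
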