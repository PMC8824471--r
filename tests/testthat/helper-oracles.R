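# Shared fixtures and independent oracles.

wt_params <- nav_parameters("WT")
ko_params <- nav_parameters("Scn4b-/-")
wt_model <- nav_model(wt_params)

# coarse control for protocol tests where sub-ms sampling accuracy is not
# under test
coarse_ctl <- protocol_control(sample_interval_ms = 0.02)

# Independent transcription of the published rate equations, structured as a
# direct formula-by-formula evaluation (no shared code with the package
# implementation). Used for the parameter-table fidelity check.
oracle_rates <- function(values, V, q10 = 3, tK = 295) {
  tf <- 1 / q10^((37 - (tK - 273)) / 10)
  g <- function(nm) values[[nm]]
  a11 <- tf * 1 / (g("a11_variable1") * exp(-V / g("a11_variable2")))
  a12 <- g("a12") * a11
  a13 <- g("a13") * a11
  b11 <- tf * 1 / (g("b11_variable1") * exp(V / g("b11_variable2")))
  b12 <- g("b12") * b11
  b13 <- g("b13") * b11
  a3 <- tf * g("a3_variable1") * exp(-V / g("a3_variable2"))
  b3 <- tf * g("b3_variable1") * exp(V / g("b3_variable2"))
  a2 <- tf * g("a2_variable1") * exp(V / g("a2_variable2"))
  a6 <- tf * g("a6_variable1") * exp(V / g("a6_variable2"))
  b6 <- tf * g("b6_variable1") * exp(-V / g("b6_variable2"))
  a2s <- tf * g("a2s_variable1") * exp(V / g("a2s_variable2"))
  b2s <- tf * g("b2s_variable1") * exp(-V / g("b2s_variable2"))
  a3s <- tf * g("a3s_variable1") * exp(-V / g("a3s_variable2"))
  b2 <- (a13 * a2 * a3) / (b13 * b3)
  b3s <- (a2s * a3s * a13) / (b2s * b13)
  c(a11 = a11, a12 = a12, a13 = a13, b11 = b11, b12 = b12, b13 = b13,
    a2 = a2, b2 = b2, a3 = a3, b3 = b3, a6 = a6, b6 = b6,
    a2s = a2s, b2s = b2s, a3s = a3s, b3s = b3s)
}

# Fine-step explicit Euler integrator (independent propagation oracle).
euler_propagate <- function(model, p0, V, dur, dt = 1e-4) {
  Q <- build_generator(model$params, V, model$scheme)
  p <- as.numeric(p0)
  n <- round(dur / dt)
  for (i in seq_len(n)) p <- p + dt * as.numeric(p %*% Q)
  setNames(p, model$scheme$states)
}

# Classic fourth-order Runge-Kutta oracle for stiffer segments.
rk4_propagate <- function(model, p0, V, dur, dt = 1e-4) {
  Q <- build_generator(model$params, V, model$scheme)
  p <- as.numeric(p0)
  n <- round(dur / dt)
  for (i in seq_len(n)) {
    k1 <- as.numeric(p %*% Q)
    k2 <- as.numeric((p + dt / 2 * k1) %*% Q)
    k3 <- as.numeric((p + dt / 2 * k2) %*% Q)
    k4 <- as.numeric((p + dt * k3) %*% Q)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  setNames(p, model$scheme$states)
}

# Post-depolarization state used by several tests: 5 ms at 0 mV from rest.
post_depol_state <- function(model = wt_model, hold = -90, dur = 5) {
  p <- steady_state(model, hold)
  propagate(p, model, 0, dur)
}
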