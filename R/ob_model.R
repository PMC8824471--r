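#' The open-channel-block (Raman-Bean) scheme topology
#'
#' Thirteen states: an activation chain C1-C5 into the open state O, a
#' parallel inactivation chain I1-I5 with vertical transitions to the closed
#' states, a fast-inactivated state I6 off the open state, and an
#' open-blocked state OB connected exclusively to O. The defining structural
#' feature is the isolation of OB: blocked channels can neither inactivate
#' nor close, and must transit back through the open/conducting state on
#' unblock, which is what produces resurgent current in this mechanism.
#'
#' The published numeric rate constants of this model are not shipped (they
#' appear only in the original reference); supply them as `rate_table`, a
#' named list of rate constants or functions of voltage (1/ms, mV), with one
#' entry per edge-rate name below. [ob_placeholder_rates()] provides a
#' clearly-labelled synthetic qualitative set for structural and
#' mechanism-contrast demonstrations.
#'
#' Edge-rate names: `alpha1..alpha4` / `beta1..beta4` (closed chain),
#' `gamma` / `delta` (C5-O), `ialpha1..ialpha4` / `ibeta1..ibeta4`
#' (inactivated chain), `con1..con5` / `coff1..coff5` (closed-inactivated
#' verticals), `oon` / `ooff` (O-I6), `block` / `unblock` (O-OB).
#'
#' @param rate_table Named list mapping every edge-rate name to a constant or
#'   a `function(V)`.
#'
#' @return A `nav_model` on the 13-state scheme.
#' @export
ob_scheme <- function(rate_table) {
  states <- c(paste0("C", 1:5), "O", "OB", paste0("I", 1:6))
  edges <- bind_rows(
    tibble(from = paste0("C", 1:4), to = paste0("C", 2:5),
           rate = paste0("alpha", 1:4)),
    tibble(from = paste0("C", 2:5), to = paste0("C", 1:4),
           rate = paste0("beta", 1:4)),
    tibble(from = "C5", to = "O", rate = "gamma"),
    tibble(from = "O", to = "C5", rate = "delta"),
    tibble(from = paste0("I", 1:4), to = paste0("I", 2:5),
           rate = paste0("ialpha", 1:4)),
    tibble(from = paste0("I", 2:5), to = paste0("I", 1:4),
           rate = paste0("ibeta", 1:4)),
    tibble(from = paste0("C", 1:5), to = paste0("I", 1:5),
           rate = paste0("con", 1:5)),
    tibble(from = paste0("I", 1:5), to = paste0("C", 1:5),
           rate = paste0("coff", 1:5)),
    tibble(from = "O", to = "I6", rate = "oon"),
    tibble(from = "I6", to = "O", rate = "ooff"),
    tibble(from = "I5", to = "I6", rate = "ialpha5"),
    tibble(from = "I6", to = "I5", rate = "ibeta5"),
    tibble(from = "O", to = "OB", rate = "block"),
    tibble(from = "OB", to = "O", rate = "unblock"))
  needed <- unique(edges$rate)
  missing <- setdiff(needed, names(rate_table))
  if (length(missing)) {
    abort(paste0("rate_table is missing edge rate(s): ", toString(missing)))
  }
  scheme <- kinetic_scheme(states, edges, conducting = "O",
                           label = "open-channel block (13-state)")
  nav_model(rate_table[needed], scheme, label = "OB model")
}

#' Synthetic qualitative rates for the open-channel-block topology
#'
#' An invented, clearly non-authoritative rate set for [ob_scheme()], built
#' only to exhibit the qualitative signature of the open-channel-block
#' mechanism: block of open channels is favored at depolarized potentials,
#' unblock is fast on hyperpolarization (producing resurgent current), the
#' blocked state is stable during maintained depolarization (hence little
#' duration-dependent attenuation), and channels exiting OB on
#' re-depolarization produce renewed transient currents. Do not use these
#' values for quantitative work; transcribe the published constants of the
#' original model instead.
#'
#' @return Named list of rate functions suitable for [ob_scheme()].
#' @export
ob_placeholder_rates <- function() {
  alpha <- function(V) 3 * exp(V / 27)
  beta <- function(V) 0.3 * exp(-V / 27)
  a <- 1.6  # allosteric factor coupling activation and inactivation
  r <- list(
    gamma = function(V) 20 * exp(V / 100),
    delta = function(V) 0.5 * exp(-V / 27),
    oon = function(V) 1.2 * exp(V / 200),
    ooff = function(V) 0.01 * exp(-V / 50),
    block = function(V) 1.6 * exp(V / 150),
    unblock = function(V) 0.025 * exp(-V / 21))
  for (i in 1:4) {
    r[[paste0("alpha", i)]] <- local({
      k <- 5 - i
      function(V) k * alpha(V)
    })
    r[[paste0("beta", i)]] <- local({
      k <- i
      function(V) k * beta(V)
    })
  }
  for (i in 1:5) {
    r[[paste0("ialpha", i)]] <- local({
      k <- max(1, 5 - i)
      function(V) k * alpha(V) * a
    })
    r[[paste0("ibeta", i)]] <- local({
      k <- i
      function(V) k * beta(V) / a
    })
    r[[paste0("con", i)]] <- local({
      f <- 0.004 * a^(i - 1)
      function(V) f
    })
    r[[paste0("coff", i)]] <- local({
      f <- 0.4 / a^(i - 1)
      function(V) f
    })
  }
  r
}

#' Contrast two gating mechanisms on the discriminating protocols
#'
#' Runs the duration-dependence and envelope protocols for two models and
#' reports, per model, the fraction of duration-dependent attenuation of the
#' peak resurgent current (1 - y at the longest prepulse), the fitted
#' attenuation time constant where a single exponential converges, and the
#' envelope deviation. Parallel fast/slow inactivation produces strong,
#' roughly exponential attenuation; the open-channel-block topology produces
#' very little.
#'
#' @param model_a,model_b `nav_model` / `nav_params` objects.
#' @param control A [protocol_control()].
#'
#' @return A tibble with one row per model: `label`,
#'   `duration_attenuation`, `duration_tau_ms`, `envelope_deviation`.
#' @export
discriminate_mechanism <- function(model_a, model_b,
                                   control = protocol_control()) {
  one <- function(model) {
    model <- as_nav_model(model)
    dc <- duration_dependence(model, control = control)
    tau <- tryCatch(
      fit_single_exponential(dc$x, dc$y, with_offset = TRUE)$tau_ms,
      error = function(e) NA_real_)
    env <- envelope_comparison(model, control = control)
    tibble(label = model$label,
           duration_attenuation = 1 - dc$y[nrow(dc)],
           duration_tau_ms = tau,
           envelope_deviation = env$envelope_deviation)
  }
  bind_rows(one(model_a), one(model_b))
}
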