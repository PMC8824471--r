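#' Nernst equilibrium potential
#'
#' `E = (R * T / F) * ln(c_out / c_in)`, reported in mV. With 151 mM external
#' and 8 mM internal sodium at 295 K this gives about +75 mV; with 50 / 15 mM
#' about +30 mV.
#'
#' @param c_out,c_in External / internal ion concentration (mM, > 0).
#' @param temperature_K Absolute temperature in kelvin.
#'
#' @return Reversal potential in mV.
#' @examples
#' nernst_potential(151, 8)
#' @export
nernst_potential <- function(c_out, c_in, temperature_K = 295) {
  if (any(!is.finite(c_out)) || any(!is.finite(c_in)) ||
      any(c_out <= 0) || any(c_in <= 0)) {
    abort("concentrations must be finite and > 0")
  }
  if (any(temperature_K <= 0)) abort("`temperature_K` must be > 0")
  R <- 8.314462618   # J / (mol K)
  F <- 96485.33212   # C / mol
  1000 * R * temperature_K / F * log(c_out / c_in)
}

#' Steady-state occupancies at a fixed voltage
#'
#' Solves `p %*% Q = 0` with `sum(p) = 1` by a least-squares null-space solve
#' of the transposed generator; if the solve is ill-conditioned it falls back
#' to a long matrix-exponential jump (1e6 ms). Entries within rounding below
#' zero are clipped and the vector renormalized.
#'
#' @param model A `nav_model` or `nav_params`.
#' @param voltage_mV Membrane potential in mV.
#'
#' @return Named numeric vector of state probabilities (sums to 1).
#' @examples
#' steady_state(nav_parameters("WT"), -90)
#' @export
steady_state <- function(model, voltage_mV) {
  model <- as_nav_model(model)
  Q <- model_generator(model, voltage_mV)
  n <- nrow(Q)
  p <- tryCatch({
    M <- rbind(t(Q), rep(1, n))
    qr.solve(M, c(rep(0, n), 1))
  }, error = function(e) NULL)
  ok <- !is.null(p) && all(is.finite(p)) &&
    max(abs(p %*% Q)) < 1e-8 && all(p > -1e-9)
  if (!ok) {
    p0 <- rep(1 / n, n)
    p <- as.numeric(cpp_jump(Q, p0, 1e6))
    if (max(abs(p %*% Q)) > 1e-6) {
      abort("steady-state solve failed: degenerate or ill-conditioned generator")
    }
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  setNames(as.numeric(p), model$scheme$states)
}

#' Propagate occupancies at a fixed voltage
#'
#' Advances a state-occupancy vector by `dt_ms` at constant voltage using the
#' matrix exponential: `p(t + dt) = p(t) %*% expm(Q * dt)`. Probabilities are
#' renormalized (with a warning) only if conservation drifts by more than
#' 1e-9.
#'
#' @param state Named numeric occupancy vector (must match the scheme's
#'   states and sum to 1).
#' @param model A `nav_model` or `nav_params`.
#' @param voltage_mV Membrane potential in mV.
#' @param dt_ms Time step in ms (>= 0; 0 returns the input).
#'
#' @return Named occupancy vector at `t + dt`.
#' @export
propagate <- function(state, model, voltage_mV, dt_ms) {
  model <- as_nav_model(model)
  if (!is.finite(dt_ms) || dt_ms < 0) abort("`dt_ms` must be >= 0")
  states <- model$scheme$states
  if (is.null(names(state)) || !setequal(names(state), states)) {
    abort("`state` must be named with the scheme's states")
  }
  state <- state[states]
  if (dt_ms == 0) return(state)
  Q <- model_generator(model, voltage_mV)
  p <- as.numeric(cpp_jump(Q, state, dt_ms))
  if (anyNA(p)) {
    abort(paste0("matrix exponential produced NaN at V = ", voltage_mV,
                 " mV, dt = ", dt_ms, " ms"))
  }
  drift <- abs(sum(p) - 1)
  if (drift > 1e-9) {
    warn(paste0("probability drift ", format(drift), "; renormalizing"))
    p <- pmax(p, 0)
    p <- p / sum(p)
  }
  setNames(p, states)
}

# ---- voltage protocols -----------------------------------------------------

#' Build a voltage-clamp protocol
#'
#' Protocols start from the steady state at a holding potential and chain
#' step and ramp segments with the pipe:
#' `vc_protocol(-90) |> vc_step(0, 5) |> vc_step(-45, 100)`.
#'
#' @param holding_mV Holding potential (mV); the initial condition is the
#'   steady state at this voltage unless overridden in [simulate_nav()].
#' @param sample_interval_ms Sampling interval for recorded traces (ms).
#' @param ramp_dV Maximum voltage increment (mV) used to discretize ramps
#'   into piecewise-constant sub-steps.
#'
#' @return An object of class `vc_protocol`.
#' @export
vc_protocol <- function(holding_mV = -90, sample_interval_ms = 0.005,
                        ramp_dV = 0.25) {
  if (sample_interval_ms <= 0) abort("`sample_interval_ms` must be > 0")
  if (ramp_dV <= 0) abort("`ramp_dV` must be > 0")
  structure(
    list(holding_mV = holding_mV,
         sample_interval_ms = sample_interval_ms,
         ramp_dV = ramp_dV,
         segments = tibble(type = character(), V_mV = numeric(),
                           duration_ms = numeric(), V_start_mV = numeric(),
                           V_end_mV = numeric(), slope_mV_per_ms = numeric())),
    class = "vc_protocol")
}

#' @rdname vc_protocol
#' @param protocol A `vc_protocol`.
#' @param voltage_mV Step potential (mV).
#' @param duration_ms Step duration (ms, > 0).
#' @export
vc_step <- function(protocol, voltage_mV, duration_ms) {
  stopifnot(inherits(protocol, "vc_protocol"))
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    abort("step `duration_ms` must be > 0")
  }
  protocol$segments <- bind_rows(
    protocol$segments,
    tibble(type = "step", V_mV = voltage_mV, duration_ms = duration_ms,
           V_start_mV = NA_real_, V_end_mV = NA_real_,
           slope_mV_per_ms = NA_real_))
  protocol
}

#' @rdname vc_protocol
#' @param from_mV,to_mV Ramp start / end potentials (mV). `from_mV` defaults
#'   to the previous segment's final voltage (or the holding potential).
#' @param slope_mV_per_ms Signed ramp slope; its sign must match the
#'   direction `from_mV -> to_mV`.
#' @export
vc_ramp <- function(protocol, to_mV, slope_mV_per_ms, from_mV = NULL) {
  stopifnot(inherits(protocol, "vc_protocol"))
  if (is.null(from_mV)) {
    segs <- protocol$segments
    from_mV <- if (nrow(segs) == 0) protocol$holding_mV else {
      last <- segs[nrow(segs), ]
      if (last$type == "step") last$V_mV else last$V_end_mV
    }
  }
  if (slope_mV_per_ms == 0 || !is.finite(slope_mV_per_ms)) {
    abort("ramp slope must be nonzero and finite")
  }
  if (sign(slope_mV_per_ms) != sign(to_mV - from_mV)) {
    abort("ramp slope sign inconsistent with V_start -> V_end direction")
  }
  dur <- (to_mV - from_mV) / slope_mV_per_ms
  protocol$segments <- bind_rows(
    protocol$segments,
    tibble(type = "ramp", V_mV = NA_real_, duration_ms = dur,
           V_start_mV = from_mV, V_end_mV = to_mV,
           slope_mV_per_ms = slope_mV_per_ms))
  protocol
}

#' @export
print.vc_protocol <- function(x, ...) {
  cat("<vc_protocol> hold ", x$holding_mV, " mV, ", nrow(x$segments),
      " segment(s), dt = ", x$sample_interval_ms, " ms\n", sep = "")
  print(x$segments)
  invisible(x)
}

# Expand a protocol into piecewise-constant sub-segments (V, dur).
expand_segments <- function(protocol) {
  segs <- protocol$segments
  if (nrow(segs) == 0) abort("protocol has no segments")
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$type == "step") {
      out[[i]] <- tibble(segment = i, V = s$V_mV, dur = s$duration_ms)
    } else {
      nsub <- max(1L, ceiling(abs(s$V_end_mV - s$V_start_mV) / protocol$ramp_dV))
      bounds <- seq(s$V_start_mV, s$V_end_mV, length.out = nsub + 1)
      mid <- (bounds[-1] + bounds[-(nsub + 1)]) / 2
      out[[i]] <- tibble(segment = i, V = mid, dur = s$duration_ms / nsub)
    }
  }
  bind_rows(out)
}

# Core engine: propagate through piecewise-constant sub-segments, sampling
# each at dt. Returns a list with time, voltage, segment id and occupancy
# matrix (row per sample). The initial sample (t = 0, holding) is included.
sim_engine <- function(model, sub, dt, init) {
  nstate <- length(model$scheme$states)
  times <- list(); volts <- list(); segids <- list(); occs <- list()
  t0 <- 0
  p <- init
  for (i in seq_len(nrow(sub))) {
    V <- sub$V[i]; dur <- sub$dur[i]
    if (abs(V) > 150 && (V < -150 || V > 60)) {
      warn(paste0("voltage ", V, " mV outside the validated range [-150, 60]"))
    }
    Q <- model_generator(model, V)
    n <- max(1L, as.integer(round(dur / dt)))
    occ <- cpp_propagate_fixed(Q, p, dur / n, n)
    tt <- t0 + seq(0, dur, length.out = n + 1)
    times[[i]] <- tt
    volts[[i]] <- rep(V, n + 1)
    segids[[i]] <- rep(sub$segment[i], n + 1)
    occs[[i]] <- occ
    p <- occ[nrow(occ), ]
    t0 <- t0 + dur
  }
  list(time = unlist(times), voltage = unlist(volts),
       segment = unlist(segids), occ = do.call(rbind, occs))
}

#' Simulate a voltage-clamp protocol
#'
#' Propagates state occupancies through a protocol with the
#' matrix-exponential technique and converts open-state probability to
#' current with an ohmic driving force, `I = g_max * P_O * (V - E_rev)`.
#' The initial condition is the steady state at the holding potential unless
#' `init` is supplied. Ramps are discretized into piecewise-constant
#' sub-steps of at most `ramp_dV` mV.
#'
#' @param model A `nav_model` or `nav_params`.
#' @param protocol A `vc_protocol`.
#' @param e_rev_mV Reversal potential (mV); +75 corresponds to the standard
#'   151 / 8 mM sodium condition, +30 to the low-sodium condition.
#' @param g_max Maximal conductance (arbitrary units, > 0). All summary
#'   quantities in the package are ratios, times or argmax voltages, so its
#'   value cancels.
#' @param init Optional named initial occupancy vector.
#'
#' @return A tibble of class `nav_trace`: `time_ms`, `voltage_mV`, `segment`,
#'   one column per state, `open_prob`, `current`. Attributes `model_label`,
#'   `e_rev_mV`, `g_max`. Segment boundaries appear twice (end of one
#'   segment, start of the next) with the respective voltages.
#' @examples
#' wt <- nav_parameters("WT")
#' pr <- vc_protocol(-90, sample_interval_ms = 0.01) |>
#'   vc_step(0, 5) |> vc_step(-45, 40)
#' tr <- simulate_nav(wt, pr)
#' @export
simulate_nav <- function(model, protocol, e_rev_mV = 75, g_max = 1,
                         init = NULL) {
  model <- as_nav_model(model)
  stopifnot(inherits(protocol, "vc_protocol"))
  if (g_max <= 0) abort("`g_max` must be > 0")
  sub <- expand_segments(protocol)
  if (is.null(init)) {
    init <- steady_state(model, protocol$holding_mV)
  } else {
    states <- model$scheme$states
    if (is.null(names(init)) || !setequal(names(init), states)) {
      abort("`init` must be named with the scheme's states")
    }
    init <- init[states]
  }
  res <- sim_engine(model, sub, protocol$sample_interval_ms, init)
  occ <- res$occ
  colnames(occ) <- model$scheme$states
  p_open <- rowSums(occ[, model$scheme$conducting, drop = FALSE])
  out <- tibble(
    time_ms = res$time, voltage_mV = res$voltage, segment = res$segment)
  out <- dplyr::bind_cols(out, as_tibble(occ))
  out$open_prob <- p_open
  out$current <- g_max * p_open * (res$voltage - e_rev_mV)
  attr(out, "model_label") <- model$label
  attr(out, "e_rev_mV") <- e_rev_mV
  attr(out, "g_max") <- g_max
  class(out) <- c("nav_trace", class(out))
  out
}
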