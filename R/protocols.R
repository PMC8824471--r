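#' Numerical control settings for protocol simulations
#'
#' Bundles the numerical choices shared by all protocol pipelines. The
#' defaults (5 us sampling of measured segments, 0.25 mV ramp discretization)
#' were chosen so that halving either changes any reported peak or time
#' constant by well under 0.1% / 0.5% respectively.
#'
#' @param sample_interval_ms Sampling interval for measured segments (ms).
#' @param ramp_dV Ramp discretization (mV per piecewise-constant sub-step).
#' @param e_rev_mV Reversal potential (mV).
#' @param inar_window_ms Length of the repolarization segment over which
#'   resurgent currents are measured (ms).
#' @param test_window_ms Length of depolarizing test steps used for peak
#'   transient measurements (ms).
#' @param tau_window_ms Window used for transient-decay time constants (ms).
#'
#' @return A list of class `protocol_control`.
#' @export
protocol_control <- function(sample_interval_ms = 0.005, ramp_dV = 0.25,
                             e_rev_mV = 75, inar_window_ms = 100,
                             test_window_ms = 20, tau_window_ms = 50) {
  stopifnot(sample_interval_ms > 0, ramp_dV > 0, inar_window_ms > 0)
  structure(list(sample_interval_ms = sample_interval_ms, ramp_dV = ramp_dV,
                 e_rev_mV = e_rev_mV, inar_window_ms = inar_window_ms,
                 test_window_ms = test_window_ms,
                 tau_window_ms = tau_window_ms),
            class = "protocol_control")
}

# ---- internal fast engine --------------------------------------------------

# Record a fixed-voltage segment: returns list(time, occ) with occ a matrix
# (rows = samples, cols = states).
record_step <- function(model, p, V, dur, dt) {
  Q <- model_generator(model, V)
  n <- max(1L, as.integer(round(dur / dt)))
  occ <- cpp_propagate_fixed(Q, p, dur / n, n)
  list(time = seq(0, dur, length.out = n + 1), occ = occ)
}

# Advance without sampling.
jump_step <- function(model, p, V, dur) {
  as.numeric(cpp_jump(model_generator(model, V), p, dur))
}

open_current <- function(model, occ, V, e_rev) {
  idx <- match(model$scheme$conducting, model$scheme$states)
  po <- if (length(idx) == 1) occ[, idx] else rowSums(occ[, idx, drop = FALSE])
  po * (V - e_rev)
}

# Peak inward current of a persistent-subtracted segment. Returns the signed
# peak (<= 0; 0 when there is no inward transient beyond the persistent
# level), its time, and the persistent level.
peak_subtracted <- function(time, current, frac = 0.05) {
  lev <- persistent_level(current, frac)
  s <- current - lev
  k <- which.min(s)
  list(peak = min(s[k], 0), time = time[k], persistent = lev)
}

new_nav_curve <- function(x, y, protocol_id, x_name = "x", y_name = "y",
                          meta = list(), extra = NULL) {
  out <- tibble(x = x, y = y)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  attr(out, "protocol_id") <- protocol_id
  attr(out, "x_name") <- x_name
  attr(out, "y_name") <- y_name
  attr(out, "meta") <- meta
  class(out) <- c("nav_curve", class(out))
  out
}

curve_meta <- function(model, control, holding) {
  list(model_label = model$label, e_rev_mV = control$e_rev_mV,
       holding_mV = holding)
}

# ---- the nine optimization protocols --------------------------------------

#' Steady-state availability curve
#'
#' For each conditioning voltage (-120 to -10 mV), the channel is equilibrated
#' to steady state, stepped to 0 mV, and the peak open probability recorded;
#' values are normalized to the -120 mV conditioning step.
#'
#' @param model A `nav_model` or `nav_params`.
#' @param voltages Conditioning voltages (mV).
#' @param control A [protocol_control()].
#'
#' @return A `nav_curve` tibble with `x` (conditioning mV) and `y`
#'   (normalized peak open probability).
#' @export
availability_curve <- function(model, voltages = seq(-120, -10, by = 5),
                               control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  pk <- map_dbl(voltages, function(vc) {
    p <- steady_state(model, vc)
    seg <- record_step(model, p, 0, control$test_window_ms, dt)
    idx <- match(model$scheme$conducting, model$scheme$states)
    max(rowSums(seg$occ[, idx, drop = FALSE]))
  })
  new_nav_curve(voltages, pk / pk[1], "availability",
                "conditioning_mV", "normalized_peak_open_prob",
                curve_meta(model, control, NA))
}

#' Steady-state activation (conductance) curve
#'
#' From steady state at -80 mV, the channel is stepped to test potentials
#' (-77 to 0 mV in 3 mV increments); the peak conductance
#' `G = I_peak / (V - E_rev) = g_max * peak P_O` at each voltage is
#' normalized to its value at 0 mV.
#'
#' @inheritParams availability_curve
#' @param holding_mV Holding potential (mV).
#' @param voltages Test potentials (mV).
#' @export
activation_curve <- function(model, voltages = seq(-77, 0, by = 3),
                             holding_mV = -80,
                             control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  idx <- match(model$scheme$conducting, model$scheme$states)
  g <- map_dbl(voltages, function(v) {
    seg <- record_step(model, p0, v, control$tau_window_ms, dt)
    max(rowSums(seg$occ[, idx, drop = FALSE]))
  })
  new_nav_curve(voltages, g / g[length(g)], "activation",
                "voltage_mV", "normalized_conductance",
                curve_meta(model, control, holding_mV))
}

#' Transient-current inactivation time constants
#'
#' From steady state at -90 mV, steps to -50..0 mV; at each voltage the 1/e
#' decay time of the persistent-subtracted transient current is measured.
#' Non-decaying traces are excluded with a warning.
#'
#' @inheritParams activation_curve
#' @export
inactivation_tau_curve <- function(model, voltages = seq(-50, 0, by = 5),
                                   holding_mV = -90,
                                   control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  taus <- map_dbl(voltages, function(v) {
    seg <- record_step(model, p0, v, control$tau_window_ms, dt)
    cur <- open_current(model, seg$occ, v, control$e_rev_mV)
    lev <- persistent_level(cur)
    tryCatch(tau_one_over_e(seg$time, cur - lev),
             error = function(e) {
               warn(paste0("no 1/e decay at ", v, " mV; point excluded"))
               NA_real_
             })
  })
  keep <- !is.na(taus)
  new_nav_curve(voltages[keep], taus[keep], "tau_inact",
                "voltage_mV", "tau_ms", curve_meta(model, control, holding_mV))
}

#' Recovery from fast inactivation
#'
#' Paired-pulse protocol: a conditioning depolarization to 0 mV, recovery at
#' the holding potential for a variable interval, then a second
#' depolarization; the curve is the ratio of the second to the first peak
#' transient current.
#'
#' @inheritParams activation_curve
#' @param intervals_ms Recovery intervals (ms).
#' @export
recovery_curve <- function(model,
                           intervals_ms = c(0.5, 1, 2, 3, 5, 7, 10, 15, 20,
                                            30, 50, 75, 100, 200, 500),
                           holding_mV = -90,
                           control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  s1 <- record_step(model, p0, 0, control$test_window_ms, dt)
  cur1 <- open_current(model, s1$occ, 0, control$e_rev_mV)
  pk1 <- min(cur1)
  p_end <- s1$occ[nrow(s1$occ), ]
  ratio <- map_dbl(intervals_ms, function(iv) {
    p <- jump_step(model, p_end, holding_mV, iv)
    s2 <- record_step(model, p, 0, control$test_window_ms, dt)
    min(open_current(model, s2$occ, 0, control$e_rev_mV)) / pk1
  })
  new_nav_curve(intervals_ms, ratio, "recovery",
                "interval_ms", "peak_ratio",
                curve_meta(model, control, holding_mV))
}

#' Persistent current fraction
#'
#' From steady state at -90 mV: 5 ms at 0 mV, then 100 ms at -45 mV; the
#' quasi-steady current at the end of the hyperpolarizing step, normalized to
#' the initial peak transient current.
#'
#' @inheritParams activation_curve
#' @return A single numeric value (dimensionless ratio, independent of
#'   `g_max`).
#' @export
persistent_fraction <- function(model, holding_mV = -90,
                                control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  s1 <- record_step(model, p0, 0, 5, dt)
  pk <- min(open_current(model, s1$occ, 0, control$e_rev_mV))
  s2 <- record_step(model, s1$occ[nrow(s1$occ), ], -45, 100, dt)
  cur2 <- open_current(model, s2$occ, -45, control$e_rev_mV)
  persistent_level(cur2) / pk
}

#' Resurgent-to-transient amplitude ratio curve
#'
#' After a 5 ms depolarization to 0 mV from steady state at -90 mV, the
#' persistent-subtracted peak resurgent current at each repolarization
#' voltage (-80 to -5 mV) is normalized to the peak transient current at
#' 0 mV.
#'
#' @inheritParams activation_curve
#' @param voltages Repolarization voltages (mV).
#' @export
resurgent_ratio_curve <- function(model, voltages = seq(-80, -5, by = 5),
                                  holding_mV = -90,
                                  control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  s1 <- record_step(model, p0, 0, 5, dt)
  pkT <- min(open_current(model, s1$occ, 0, control$e_rev_mV))
  p_end <- s1$occ[nrow(s1$occ), ]
  pkR <- map_dbl(voltages, function(v) {
    seg <- record_step(model, p_end, v, control$inar_window_ms, dt)
    cur <- open_current(model, seg$occ, v, control$e_rev_mV)
    peak_subtracted(seg$time, cur)$peak
  })
  new_nav_curve(voltages, pkR / pkT, "inar_ratio",
                "voltage_mV", "inar_over_inat",
                curve_meta(model, control, holding_mV))
}

#' Duration dependence of the resurgent current
#'
#' From steady state at -90 mV the channel is depolarized to +20 mV for 2 to
#' 36 ms, then repolarized to -45 mV; persistent-subtracted peak resurgent
#' amplitudes are normalized to the 2 ms prepulse.
#'
#' @inheritParams activation_curve
#' @param durations_ms Prepulse durations (ms).
#' @param prepulse_mV Prepulse potential (mV).
#' @param repol_mV Repolarization potential (mV).
#' @export
duration_dependence <- function(model, durations_ms = seq(2, 36, by = 2),
                                prepulse_mV = 20, repol_mV = -45,
                                holding_mV = -90,
                                control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  pk <- map_dbl(durations_ms, function(d) {
    p <- jump_step(model, p0, prepulse_mV, d)
    seg <- record_step(model, p, repol_mV, control$inar_window_ms, dt)
    cur <- open_current(model, seg$occ, repol_mV, control$e_rev_mV)
    peak_subtracted(seg$time, cur)$peak
  })
  new_nav_curve(durations_ms, pk / pk[1], "duration",
                "prepulse_duration_ms", "normalized_peak_inar",
                curve_meta(model, control, holding_mV))
}

#' Resurgent-current decay time constants
#'
#' After a 5 ms depolarization to 0 mV, single-exponential time constants of
#' the persistent-subtracted resurgent-current decay at repolarization
#' voltages -45 to -5 mV.
#'
#' @inheritParams resurgent_ratio_curve
#' @export
resurgent_decay_taus <- function(model, voltages = seq(-45, -5, by = 5),
                                 holding_mV = -90,
                                 control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  p_end <- record_step(model, p0, 0, 5, dt)$occ
  p_end <- p_end[nrow(p_end), ]
  taus <- map_dbl(voltages, function(v) {
    seg <- record_step(model, p_end, v, control$inar_window_ms, dt)
    cur <- open_current(model, seg$occ, v, control$e_rev_mV)
    ps <- peak_subtracted(seg$time, cur)
    sub <- cur - ps$persistent
    k <- which.min(sub)
    dec_t <- seg$time[k:length(sub)] - seg$time[k]
    dec_y <- -sub[k:length(sub)]  # positive, decaying magnitude
    if (length(dec_t) > 250) {  # thin dense traces before the fit
      pick <- unique(round(seq(1, length(dec_t), length.out = 250)))
      dec_t <- dec_t[pick]
      dec_y <- dec_y[pick]
    }
    out <- tryCatch(
      fit_single_exponential(dec_t, dec_y, with_offset = FALSE)$tau_ms,
      error = function(e) {
        warn(paste0("resurgent decay fit failed at ", v,
                    " mV; point excluded"))
        NA_real_
      })
    out
  })
  keep <- !is.na(taus)
  new_nav_curve(voltages[keep], taus[keep], "inar_tau",
                "voltage_mV", "tau_ms", curve_meta(model, control, holding_mV))
}

#' Voltage independence of the peak resurgent current
#'
#' 5 ms prepulses to -35..-5 mV (optionally any set of potentials) followed
#' by repolarization to -45 mV; reports the per-voltage peak resurgent
#' currents and their coefficient of variation.
#'
#' @inheritParams activation_curve
#' @param prepulse_mV Prepulse potentials (mV).
#'
#' @return A list with `peaks` (a `nav_curve`: prepulse mV vs peak current)
#'   and `cv` (coefficient of variation of the peaks).
#' @export
prepulse_peak_spread <- function(model, prepulse_mV = seq(-35, -5, by = 5),
                                 holding_mV = -90,
                                 control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  pk <- map_dbl(prepulse_mV, function(vp) {
    p <- jump_step(model, p0, vp, 5)
    seg <- record_step(model, p, -45, control$inar_window_ms, dt)
    cur <- open_current(model, seg$occ, -45, control$e_rev_mV)
    peak_subtracted(seg$time, cur)$peak
  })
  list(peaks = new_nav_curve(prepulse_mV, pk, "prepulse",
                             "prepulse_mV", "peak_inar",
                             curve_meta(model, control, holding_mV)),
       cv = sd(pk) / abs(mean(pk)))
}

# ---- figure-level paradigms ------------------------------------------------

#' Voltage dependence of the peak resurgent current
#'
#' The classic resurgent-current paradigm: from a holding potential of
#' -80 mV, a 5 ms depolarization to 0 mV followed by repolarizations to -70
#' to -10 mV. Reports persistent-subtracted peak resurgent amplitudes (raw
#' and normalized to the largest).
#'
#' @inheritParams resurgent_ratio_curve
#' @return A `nav_curve` with `x` (repolarization mV), `y` (normalized peak),
#'   a `peak` column (signed current) and attribute `v_max_mV` (the voltage
#'   of maximal resurgent current).
#' @export
resurgent_voltage_curve <- function(model, voltages = seq(-70, -10, by = 5),
                                    holding_mV = -80,
                                    control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  s1 <- record_step(model, p0, 0, 5, dt)
  p_end <- s1$occ[nrow(s1$occ), ]
  pk <- map_dbl(voltages, function(v) {
    seg <- record_step(model, p_end, v, control$inar_window_ms, dt)
    cur <- open_current(model, seg$occ, v, control$e_rev_mV)
    peak_subtracted(seg$time, cur)$peak
  })
  out <- new_nav_curve(voltages, pk / min(pk), "inar_voltage",
                       "voltage_mV", "normalized_peak_inar",
                       curve_meta(model, control, holding_mV),
                       extra = tibble(peak = pk))
  attr(out, "v_max_mV") <- voltages[which.min(pk)]
  out
}

#' Sequential recovery of transient and resurgent currents
#'
#' Two identical sweeps (5 ms at 0 mV then 100 ms at -45 mV) separated by a
#' brief 20 ms step to -90 mV. Returns the second-to-first peak ratios for
#' the transient (at 0 mV) and resurgent (at -45 mV) components. The
#' single-population model yields approximately equal ratios; it does not
#' produce the differential recovery seen experimentally.
#'
#' @inheritParams activation_curve
#' @param gap_ms Recovery gap at the holding potential (ms).
#' @return A tibble with `component` and `relative` columns.
#' @export
sequential_recovery <- function(model, gap_ms = 20, holding_mV = -90,
                                control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p <- steady_state(model, holding_mV)
  sweep <- function(p) {
    s1 <- record_step(model, p, 0, 5, dt)
    pkT <- min(open_current(model, s1$occ, 0, control$e_rev_mV))
    s2 <- record_step(model, s1$occ[nrow(s1$occ), ], -45, 100, dt)
    cur <- open_current(model, s2$occ, -45, control$e_rev_mV)
    pkR <- peak_subtracted(s2$time, cur)$peak
    list(pkT = pkT, pkR = pkR, p = s2$occ[nrow(s2$occ), ])
  }
  w1 <- sweep(p)
  p2 <- jump_step(model, w1$p, holding_mV, gap_ms)
  w2 <- sweep(p2)
  tibble(component = c("I_NaT", "I_NaR"),
         relative = c(w2$pkT / w1$pkT, w2$pkR / w1$pkR))
}

#' Envelope test: sustained versus repetitive repolarizations
#'
#' Compares the resurgent current during one sustained 80 ms repolarization
#' to -45 mV (after 5 ms at 0 mV) with the peaks of successive brief (2 ms)
#' repolarizations to -45 mV interspersed with 5 ms depolarizations to 0 mV.
#' Peaks are compared with the sustained trace at matched (wall-clock) times
#' from the start of the first repolarization.
#'
#' @inheritParams activation_curve
#' @param n_cycles Number of 2 ms repolarization / 5 ms depolarization
#'   cycles.
#' @return A list with `sustained` (tibble: time_ms, current),
#'   `repetitive` (tibble: time_ms, peak), `envelope_deviation`
#'   (max relative mismatch) and `is_occupancy` (tibble of slow-inactivated
#'   occupancy under both protocols at cycle boundaries).
#' @export
envelope_comparison <- function(model, n_cycles = 11, holding_mV = -90,
                                control = protocol_control()) {
  model <- as_nav_model(model)
  dt <- control$sample_interval_ms
  p0 <- steady_state(model, holding_mV)
  s1 <- record_step(model, p0, 0, 5, dt)
  p_start <- s1$occ[nrow(s1$occ), ]
  sus <- record_step(model, p_start, -45, 80, dt)
  cur_sus <- open_current(model, sus$occ, -45, control$e_rev_mV)
  lev <- persistent_level(cur_sus)
  is_idx <- match("IS", model$scheme$states)
  p <- p_start
  peaks <- numeric(n_cycles); tpk <- numeric(n_cycles)
  is_rep <- numeric(n_cycles); wall <- 0
  for (i in seq_len(n_cycles)) {
    seg <- record_step(model, p, -45, 2, dt)
    cur <- open_current(model, seg$occ, -45, control$e_rev_mV)
    k <- which.min(cur - lev)
    peaks[i] <- cur[k] - lev
    tpk[i] <- wall + seg$time[k]
    p <- seg$occ[nrow(seg$occ), ]
    if (!is.na(is_idx)) is_rep[i] <- p[is_idx]
    wall <- wall + 2
    p <- jump_step(model, p, 0, 5)
    wall <- wall + 5
  }
  sus_at <- approx(sus$time, cur_sus - lev, xout = pmin(tpk, 80))$y
  dev <- max(abs((peaks - sus_at) / sus_at))
  is_sus <- if (!is.na(is_idx)) {
    approx(sus$time, sus$occ[, is_idx], xout = pmin(tpk, 80))$y
  } else rep(NA_real_, n_cycles)
  list(
    sustained = tibble(time_ms = sus$time, current = cur_sus),
    repetitive = tibble(time_ms = tpk, peak = peaks,
                        sustained_at = sus_at),
    envelope_deviation = dev,
    is_occupancy = tibble(time_ms = tpk, repetitive = is_rep,
                          sustained = is_sus))
}

#' Current during slow voltage ramps
#'
#' A depolarizing ramp (-100 to 0 mV) reveals only the persistent current; a
#' hyperpolarizing ramp (0 to -100 mV, from steady state at 0 mV) reveals the
#' persistent plus resurgent components. Default slope 0.12 mV/ms; output
#' sampled at <= 2 ms.
#'
#' @inheritParams activation_curve
#' @param direction `"up"` or `"down"`.
#' @param slope_mV_per_ms Ramp speed magnitude.
#' @return A `nav_curve` with `x` (instantaneous mV) and `y` (current).
#' @export
ramp_current <- function(model, direction = c("up", "down"),
                         slope_mV_per_ms = 0.12,
                         control = protocol_control()) {
  direction <- match.arg(direction)
  model <- as_nav_model(model)
  from <- if (direction == "up") -100 else 0
  to <- if (direction == "up") 0 else -100
  slope <- if (direction == "up") slope_mV_per_ms else -slope_mV_per_ms
  pr <- vc_protocol(from, sample_interval_ms = 2, ramp_dV = control$ramp_dV) |>
    vc_ramp(to, slope)
  tr <- simulate_nav(model, pr, e_rev_mV = control$e_rev_mV)
  tr <- tr[!duplicated(tr$time_ms), ]
  # instantaneous ramp voltage at each sample (sub-step midpoints are an
  # engine detail; report the nominal ramp voltage)
  v_nominal <- from + slope * tr$time_ms
  new_nav_curve(v_nominal, tr$current, paste0("ramp_", direction),
                "voltage_mV", "current",
                curve_meta(model, control, from))
}

# Registry used by the optimization module and the CLI.
protocol_registry <- function() {
  list(
    availability = function(model, control)
      availability_curve(model, control = control),
    activation = function(model, control)
      activation_curve(model, control = control),
    tau_inact = function(model, control)
      inactivation_tau_curve(model, control = control),
    recovery = function(model, control)
      recovery_curve(model, control = control),
    persistent = function(model, control) {
      model <- as_nav_model(model)
      new_nav_curve(0, persistent_fraction(model, control = control),
                    "persistent", "dummy", "fraction",
                    curve_meta(model, control, -90))
    },
    inar_ratio = function(model, control)
      resurgent_ratio_curve(model, control = control),
    duration = function(model, control)
      duration_dependence(model, control = control),
    inar_tau = function(model, control)
      resurgent_decay_taus(model, control = control),
    prepulse = function(model, control)
      prepulse_peak_spread(model, control = control)$peaks)
}

#' Run one optimization protocol by id
#'
#' Protocol ids: `availability`, `activation`, `tau_inact`, `recovery`,
#' `persistent`, `inar_ratio`, `duration`, `inar_tau`, `prepulse`.
#'
#' @inheritParams availability_curve
#' @param id Protocol id.
#' @return A `nav_curve`.
#' @export
run_protocol <- function(model, id, control = protocol_control()) {
  reg <- protocol_registry()
  if (!id %in% names(reg)) {
    abort(paste0("unknown protocol id '", id, "'; available: ",
                 toString(names(reg))))
  }
  reg[[id]](model, control)
}
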