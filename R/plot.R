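#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a simulated voltage-clamp trace
#'
#' Voltage command (top) and current (bottom) against time.
#'
#' @param object A `nav_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nav_trace
#' @export
autoplot.nav_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("time_ms", "voltage_mV", "current")],
    c("voltage_mV", "current"), names_to = "signal", values_to = "value")
  df$signal <- factor(df$signal, levels = c("voltage_mV", "current"))
  ggplot(df, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~signal, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL,
         title = paste0("model: ", attr(object, "model_label"))) +
    theme_minimal()
}

#' Plot a summary curve
#'
#' @param object A `nav_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nav_curve
#' @export
autoplot.nav_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_line(linewidth = 0.4) + geom_point(size = 1.2) +
    labs(x = attr(object, "x_name"), y = attr(object, "y_name"),
         title = attr(object, "protocol_id")) +
    theme_minimal()
}

#' Plot state occupancies of a trace
#'
#' Occupancy of every gating state against time; useful for visualizing the
#' separation of the fast (IF1/IF2) and slow (IS) inactivation pathways.
#'
#' @param trace A `nav_trace`.
#' @param states Optional subset of state names.
#' @return A ggplot object.
#' @export
plot_occupancies <- function(trace, states = NULL) {
  keep <- setdiff(colnames(trace),
                  c("time_ms", "voltage_mV", "segment", "open_prob",
                    "current"))
  if (!is.null(states)) keep <- intersect(keep, states)
  df <- tidyr::pivot_longer(trace[, c("time_ms", keep)], -"time_ms",
                            names_to = "state", values_to = "occupancy")
  ggplot(df, aes(x = .data$time_ms, y = .data$occupancy,
                 colour = .data$state)) +
    geom_line(linewidth = 0.4) +
    labs(x = "time (ms)", y = "occupancy") +
    theme_minimal()
}

#' Plot an exponential or Boltzmann fit over its data
#'
#' @param object A `nav_exp_fit` or `nav_boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nav_exp_fit
#' @export
autoplot.nav_exp_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot(df, aes(x = .data$x)) +
    geom_point(aes(y = .data$y), size = 1.2) +
    geom_line(aes(y = .data$fitted), colour = "red3") +
    labs(x = "x", y = "y",
         title = sprintf("single exponential: tau = %.3g ms", object$tau_ms)) +
    theme_minimal()
}

#' @rdname autoplot.nav_exp_fit
#' @method autoplot nav_boltzmann_fit
#' @export
autoplot.nav_boltzmann_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot(df, aes(x = .data$V)) +
    geom_point(aes(y = .data$y), size = 1.2) +
    geom_line(aes(y = .data$fitted), colour = "red3") +
    labs(x = "voltage (mV)", y = "normalized",
         title = sprintf("Boltzmann: V1/2 = %.3g mV, k = %.3g mV",
                         object$v_half_mV, object$slope_mV)) +
    theme_minimal()
}
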