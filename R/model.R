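#' Bundle parameters and a scheme into a simulatable model
#'
#' A `nav_model` couples a rate source (a `nav_params` object, or a named list
#' of per-edge rate functions for custom topologies such as [ob_scheme()])
#' with a `kinetic_scheme`. All protocol and simulation functions accept
#' either a `nav_model` or a bare `nav_params` (which implies the nine-state
#' scheme).
#'
#' @param params Rate source: `nav_params` or named list of rate
#'   functions/constants.
#' @param scheme A `kinetic_scheme`.
#' @param label Model label; defaults to the parameter label.
#'
#' @return An object of class `nav_model`.
#' @export
nav_model <- function(params, scheme = nav_scheme(), label = NULL) {
  if (is.null(label)) {
    label <- if (inherits(params, "nav_params")) params$label else scheme$label
  }
  # fail fast on unresolvable rate names, and precompute the edge indexing
  # used by the fast generator path
  invisible(build_generator(params, -90, scheme))
  rate_names <- names(rate_table(params, -90))
  structure(
    list(params = params, scheme = scheme, label = label,
         n_states = length(scheme$states),
         edge_cells = cbind(match(scheme$edges$from, scheme$states),
                            match(scheme$edges$to, scheme$states)),
         rate_pos = match(scheme$edges$rate, rate_names)),
    class = "nav_model")
}

as_nav_model <- function(x) {
  if (inherits(x, "nav_model")) return(x)
  if (inherits(x, "nav_params")) return(nav_model(x))
  abort("expected a `nav_model` or `nav_params` object")
}

#' @export
print.nav_model <- function(x, ...) {
  cat("<nav_model> ", x$label, " on ", length(x$scheme$states),
      "-state scheme\n", sep = "")
  invisible(x)
}

# Fast, nameless generator assembly used by the simulation engine.
model_generator <- function(model, voltage_mV) {
  r <- rate_table(model$params, voltage_mV)
  n <- model$n_states
  Q <- matrix(0, n, n)
  Q[model$edge_cells] <- r[model$rate_pos]
  diag(Q) <- -rowSums(Q)
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}
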