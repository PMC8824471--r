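#' Names of the 24 free rate parameters
#'
#' The free parameters of the nine-state gating model, in their conventional
#' order. Each voltage-dependent rate is described by one or two entries:
#' `*_variable1` is a magnitude (amplitude or denominator prefactor) and
#' `*_variable2` a voltage slope denominator in mV; the pure multipliers
#' (`a12`, `a13`, `b12`, `b13`) scale the first activation/deactivation rate.
#'
#' @return Character vector of length 24.
#' @export
nav_param_names <- function() {
  c("a11_variable1", "a11_variable2", "a12", "a13",
    "b11_variable1", "b11_variable2", "b12", "b13",
    "a3_variable1", "a3_variable2", "b3_variable1", "b3_variable2",
    "a2_variable1", "a2_variable2", "a6_variable1", "a6_variable2",
    "b6_variable1", "b6_variable2", "a2s_variable1", "a2s_variable2",
    "b2s_variable1", "b2s_variable2", "a3s_variable1", "a3s_variable2")
}

# Optimized parameter columns for the two shipped model variants.
.nav_param_table <- function() {
  list(
    "WT" = c(2.3989e-02, 9.6108e+02, 8.5613e+02, 7.2682e+01,
             1.7233e-01, 1.9691e+01, 8.8549e+01, 1.4841e+02,
             3.6734e-01, 9.8034e+02, 5.3241e+01, 1.4204e+01,
             8.7852e+01, 9.9972e+02, 6.0921e+02, 8.6490e+01,
             1.5645e+02, 3.0317e+01, 1.5817e+01, 9.9982e+02,
             1.0010e-03, 1.1963e+01, 4.4773e-03, 9.9993e+02),
    "Scn4b-/-" = c(2.0761e-02, 9.7685e+02, 8.3340e+02, 6.1087e+01,
                   1.6995e-01, 1.8560e+01, 9.3042e+01, 1.7914e+02,
                   3.9273e-01, 9.8807e+02, 4.7402e+01, 1.3469e+01,
                   8.1085e+01, 9.9984e+02, 6.0756e+02, 7.8591e+01,
                   1.6214e+02, 4.3656e+01, 2.3130e+01, 9.9969e+02,
                   1.0208e-03, 1.1383e+01, 2.8677e-03, 9.8330e+02))
}

#' Construct a rate-parameter set
#'
#' Bundles the 24 free rate parameters of the nine-state Nav gating model with
#' the temperature-scaling settings (Q10 and absolute temperature). The two
#' published variants are available by label via [nav_parameters()]; this
#' constructor is for custom sets.
#'
#' @param values Named numeric vector with exactly the names of
#'   [nav_param_names()], all strictly positive. Units follow the working
#'   convention of the package: voltages in mV, time in ms, rates in 1/ms.
#' @param q10 Temperature coefficient (dimensionless, > 0). Default 3.
#' @param temperature_K Absolute temperature in kelvin (> 0). Default 295
#'   (room temperature).
#' @param label Free-text label for the variant.
#'
#' @return An object of class `nav_params`.
#' @export
new_nav_params <- function(values, q10 = 3, temperature_K = 295,
                           label = "custom") {
  nm <- nav_param_names()
  if (is.null(names(values)) || !setequal(names(values), nm) ||
      anyDuplicated(names(values))) {
    missing <- setdiff(nm, names(values))
    extra <- setdiff(names(values), nm)
    abort(paste0(
      "`values` must carry exactly the 24 rate-parameter names.",
      if (length(missing)) paste0(" Missing: ", toString(missing), "."),
      if (length(extra)) paste0(" Unknown: ", toString(extra), ".")))
  }
  values <- values[nm]
  if (!all(is.finite(values)) || any(values <= 0)) {
    bad <- nm[!is.finite(values) | values <= 0]
    abort(paste0("All rate parameters must be finite and strictly positive; ",
                 "offending: ", toString(bad)))
  }
  if (!is.finite(q10) || q10 <= 0) abort("`q10` must be > 0")
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    abort("`temperature_K` must be > 0")
  }
  structure(
    list(values = values, q10 = q10, temperature_K = temperature_K,
         label = label),
    class = "nav_params")
}

#' Published rate-parameter sets
#'
#' Returns the optimized 24-parameter set for one of the two published model
#' variants: the wild-type Purkinje-neuron Nav model (`"WT"`) or the refit for
#' neurons lacking the Navbeta4 accessory subunit (`"Scn4b-/-"`).
#'
#' @param label `"WT"` or `"Scn4b-/-"` (alias `"scn4b"`).
#' @inheritParams new_nav_params
#'
#' @return A `nav_params` object.
#' @examples
#' wt <- nav_parameters("WT")
#' wt
#' @export
nav_parameters <- function(label = c("WT", "Scn4b-/-", "scn4b"),
                           q10 = 3, temperature_K = 295) {
  label <- match.arg(label)
  if (label == "scn4b") label <- "Scn4b-/-"
  tab <- .nav_param_table()
  new_nav_params(setNames(tab[[label]], nav_param_names()),
                 q10 = q10, temperature_K = temperature_K, label = label)
}

#' @export
print.nav_params <- function(x, ...) {
  cat("<nav_params> ", x$label, "  (Q10 = ", x$q10,
      ", T = ", x$temperature_K, " K)\n", sep = "")
  print(round(x$values, 6))
  invisible(x)
}

#' @method as_tibble nav_params
#' @export
as_tibble.nav_params <- function(x, ...) {
  tibble(parameter = names(x$values), value = unname(x$values),
         label = x$label)
}

#' Temperature scaling factor for transition rates
#'
#' Q10-based scaling from body temperature (37 C) down to the working
#' temperature: `1 / q10^((37 - (T - 273)) / 10)`. At `q10 = 1` or at
#' `T = 310 K` the factor is 1.
#'
#' @param q10 Temperature coefficient (> 0).
#' @param temperature_K Absolute temperature in kelvin (> 0).
#'
#' @return Dimensionless scaling factor.
#' @examples
#' temperature_factor(3, 295)  # ~0.1925 at room temperature
#' @export
temperature_factor <- function(q10, temperature_K) {
  if (!all(is.finite(q10)) || any(q10 <= 0)) abort("`q10` must be > 0")
  if (!all(is.finite(temperature_K)) || any(temperature_K <= 0)) {
    abort("`temperature_K` must be > 0")
  }
  1 / q10^((37 - (temperature_K - 273)) / 10)
}

#' Read a rate-parameter file
#'
#' Parameter files are flat key-value text: one `key value` pair per line
#' (whitespace separated; `#` starts a comment). The 24 rate-parameter keys
#' are required; `q10`, `temperature_K` and `label` are optional.
#'
#' @param path Path to the parameter file.
#' @return A `nav_params` object.
#' @seealso [write_nav_params()]; shipped fixtures under
#'   `system.file("extdata", package = "resurgenav")`.
#' @export
read_nav_params <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  bad <- lengths(parts) != 2
  if (any(bad)) {
    abort(paste0("malformed parameter line(s): ",
                 toString(lines[bad])))
  }
  keys <- vapply(parts, `[[`, "", 1)
  vals <- vapply(parts, `[[`, "", 2)
  if (anyDuplicated(keys)) {
    abort(paste0("duplicate key(s): ", toString(unique(keys[duplicated(keys)]))))
  }
  kv <- setNames(as.list(vals), keys)
  q10 <- if (!is.null(kv$q10)) as.numeric(kv$q10) else 3
  tK <- if (!is.null(kv$temperature_K)) as.numeric(kv$temperature_K) else 295
  label <- if (!is.null(kv$label)) kv$label else basename(path)
  rate_keys <- setdiff(keys, c("q10", "temperature_K", "label"))
  values <- setNames(as.numeric(vals[match(rate_keys, keys)]), rate_keys)
  if (anyNA(values)) {
    abort(paste0("non-numeric value for: ",
                 toString(rate_keys[is.na(values)])))
  }
  missing <- setdiff(nav_param_names(), rate_keys)
  if (length(missing)) {
    abort(paste0("parameter file is missing key(s): ", toString(missing)))
  }
  new_nav_params(values, q10 = q10, temperature_K = tK, label = label)
}

#' Write a rate-parameter file
#'
#' @param params A `nav_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nav_params <- function(params, path) {
  stopifnot(inherits(params, "nav_params"))
  lines <- c(
    paste("label", params$label),
    paste("q10", format(params$q10, digits = 15)),
    paste("temperature_K", format(params$temperature_K, digits = 15)),
    paste(names(params$values), format(params$values, digits = 15, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}
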