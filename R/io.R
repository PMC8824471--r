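#' Load a rate-parameter file
#'
#' Alias for [read_nav_params()], kept as the verb used by the command-line
#' interface.
#'
#' @inheritParams read_nav_params
#' @return A `nav_params`.
#' @export
load_parameters <- function(path) read_nav_params(path)

# Short stable hash of a parameter set, recorded in output headers for
# provenance (djb2 over the formatted values; no external digest dependency).
params_hash <- function(params) {
  s <- paste(format(params$values, digits = 15), collapse = ",")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Write a simulation trace to CSV
#'
#' Comma-separated, '.' decimal, UTF-8; times in ms, voltages in mV,
#' currents in normalized units (g_max = 1 by default). A comment header
#' records the model label, reversal potential and parameter hash.
#'
#' @param trace A `nav_trace`.
#' @param path Output path.
#' @param params Optional `nav_params` used to add a parameter hash to the
#'   header.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, params = NULL) {
  hdr <- paste0("# model=", attr(trace, "model_label"),
                " e_rev_mV=", attr(trace, "e_rev_mV"),
                " g_max=", attr(trace, "g_max"),
                if (!is.null(params)) paste0(" params_hash=",
                                             params_hash(params)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' Write a summary curve to CSV
#'
#' @param curve A `nav_curve`.
#' @param path Output path.
#' @param params Optional `nav_params` for the provenance header.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, params = NULL) {
  meta <- attr(curve, "meta")
  hdr <- paste0("# protocol=", attr(curve, "protocol_id"),
                " x=", attr(curve, "x_name"), " y=", attr(curve, "y_name"),
                if (!is.null(meta$model_label)) paste0(" model=",
                                                       meta$model_label),
                if (!is.null(meta$e_rev_mV)) paste0(" e_rev_mV=",
                                                    meta$e_rev_mV),
                if (!is.null(params)) paste0(" params_hash=",
                                             params_hash(params)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}
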