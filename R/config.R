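# YAML pipeline configuration. A config describes one construct (system),
# the initial concentrations, the measurement protocol, fit options and the
# theory table. Round-trips losslessly through write/read.

#' Read and validate a pipeline configuration
#'
#' The config is a YAML file with blocks `system` (rate constants and
#' construct metadata), `initial` (concentrations, nM), `protocol`
#' (sampling/noise parameters for synthetic generation), optional `fit`
#' (estimation options, including `exclude_before` for the pre-reaction
#' stabilization window) and optional `theory` (toehold length -> rate).
#' Missing or malformed keys raise a config error naming the key.
#'
#' @param path Path to a YAML config, or an already-parsed list.
#' @return A `tmsdr_config` list with elements `system`, `initial`,
#'   `protocol`, `fit`, `theory`, `exclude_before`.
#' @export
read_tmsdr_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(raw$system)) stop_config("config is missing the `system` block")
  for (key in c("ka", "kd")) {
    if (is.null(raw$system[[key]]))
      stop_config("config is missing required key `%s` in the system block", key)
  }
  sys_args <- raw$system[intersect(names(raw$system),
                                   names(formals(tmsdr_system)))]
  system <- do.call(tmsdr_system, sys_args)

  init <- raw$initial %||% list(x1 = 10, x2 = 10, x3 = 0, x4 = 0)
  for (key in c("x1", "x2")) {
    if (is.null(init[[key]]))
      stop_config("config is missing required key `%s` in the initial block", key)
  }
  initial <- reaction_state(init$x1, init$x2, init$x3 %||% 0, init$x4 %||% 0)

  protocol <- NULL
  if (!is.null(raw$protocol)) {
    if (is.null(raw$protocol$seed))
      stop_config("config is missing required key `seed` in the protocol block")
    prot_args <- raw$protocol[intersect(names(raw$protocol),
                                        names(formals(synthetic_protocol)))]
    protocol <- do.call(synthetic_protocol, prot_args)
  }

  fitb <- raw$fit %||% list()
  fit_args <- fitb[intersect(names(fitb), names(formals(fit_options)))]
  fit <- do.call(fit_options, fit_args)

  theory <- if (is.null(raw$theory)) theoretical_rate_table()
            else theoretical_rate_table(unlist(raw$theory))

  structure(list(system = system, initial = initial, protocol = protocol,
                 fit = fit, theory = theory,
                 exclude_before = fitb$exclude_before %||% 0),
            class = "tmsdr_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `tmsdr_config` (or compatible list).
#' @param path Output path.
#' @export
write_tmsdr_config <- function(config, path) {
  out <- list(system = unclass(config$system),
              initial = as.list(config$initial),
              protocol = if (!is.null(config$protocol)) unclass(config$protocol),
              fit = c(unclass(config$fit),
                      list(exclude_before = config$exclude_before %||% 0)),
              theory = unclass(config$theory))
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}
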