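# Classed conditions so callers (and the CLI wrapper) can map failures to
# distinct exit codes: config errors, data errors, convergence failures.

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tmsdr_config_error", "tmsdr_error", "error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tmsdr_data_error", "tmsdr_error", "error")))
}

stop_convergence <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tmsdr_convergence_error", "tmsdr_error", "error")))
}

stop_internal <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tmsdr_internal_error", "tmsdr_error", "error")))
}
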