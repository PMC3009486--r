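# Structured error conditions so the CLI can map failures to exit codes:
# input errors (bad data) vs internal consistency failures (bugs).

stop_input <- function(msg, ...) {
  stop(structure(
    class = c("mrsrf_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_internal <- function(msg, ...) {
  stop(structure(
    class = c("mrsrf_internal_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_usage <- function(msg, ...) {
  stop(structure(
    class = c("mrsrf_usage_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
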