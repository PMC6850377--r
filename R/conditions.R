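# Classed error conditions so callers (and the CLI) can map failures to
# specific exit codes without string matching.

nm_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "nestmax_error", "error")))
}

nm_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "nestmax_warning", "warning")))
}
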