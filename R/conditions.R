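# Classed conditions so the CLI can map failures to exit codes:
# schema/config errors -> 2, data errors -> 3, internal invariant breaches -> 4.

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("pfscreen_schema_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pfscreen_data_error", "error")))
}

stop_internal <- function(...) {
  stop(errorCondition(paste0(...), class = c("pfscreen_internal_error", "error")))
}
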