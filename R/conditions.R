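# Classed error helpers used across the package so callers can condition on
# failure mode rather than message text.

abort_arisacomp <- function(message, class) {
  stop(structure(
    class = c(class, "arisacomp_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

schema_error     <- function(msg) abort_arisacomp(msg, "arisacomp_schema_error")
parse_error      <- function(msg) abort_arisacomp(msg, "arisacomp_parse_error")
validation_error <- function(msg) abort_arisacomp(msg, "arisacomp_validation_error")
empty_input_error<- function(msg) abort_arisacomp(msg, "arisacomp_empty_input_error")
type_error       <- function(msg) abort_arisacomp(msg, "arisacomp_type_error")
join_error       <- function(msg) abort_arisacomp(msg, "arisacomp_join_error")
config_error     <- function(msg) abort_arisacomp(msg, "arisacomp_config_error")
undefined_value_error <- function(msg) abort_arisacomp(msg, "arisacomp_undefined_value_error")
stage_error <- function(stage, msg) {
  abort_arisacomp(sprintf("[stage: %s] %s", stage, msg), "arisacomp_stage_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
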