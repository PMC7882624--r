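## Structured conditions so callers (and the CLI) can map failures to exit
## codes: validation/schema/config -> 2, I/O -> 3.

um_stop <- function(message, class) {
  stop(structure(
    class = c(class, "um_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

um_validation_error <- function(message) {
  um_stop(message, "um_validation_error")
}

um_schema_error <- function(message) {
  um_stop(message, c("um_schema_error", "um_validation_error"))
}

um_config_error <- function(message) {
  um_stop(message, c("um_config_error", "um_validation_error"))
}

um_io_error <- function(message) {
  um_stop(message, "um_io_error")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
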