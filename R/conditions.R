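# Classed conditions used across the pipeline. Errors abort a single-image
# call; the validation harness catches them per item and carries on.

spindex_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "spindex_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

spindex_warning <- function(class, message) {
  warning(structure(
    class = c(class, "spindex_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_empty_scribble <- function(msg = "mask contains no foreground (ink) pixels") {
  spindex_error("EmptyScribble", msg)
}

stop_invalid_measurement <- function(msg) {
  spindex_error("InvalidMeasurement", msg)
}

stop_invalid_params <- function(msg) {
  spindex_error("InvalidParams", msg)
}

stop_degenerate_input <- function(msg) {
  spindex_error("DegenerateInput", msg)
}

stop_io_failure <- function(msg) {
  spindex_error("IOFailure", msg)
}
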