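# Structured error conditions. Exit-code mapping used by the CLI:
#   ws_validation_error -> 2, ws_computation_error -> 3, ws_degenerate_error -> 4

ws_abort <- function(message, class, ..., call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "ws_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

ws_validation_error <- function(message, ...) {
  ws_abort(message, "ws_validation_error", ..., call = sys.call(-1))
}

ws_computation_error <- function(message, ...) {
  ws_abort(message, "ws_computation_error", ..., call = sys.call(-1))
}

ws_degenerate_error <- function(message, ...) {
  ws_abort(message, "ws_degenerate_error", ..., call = sys.call(-1))
}

ws_exit_status <- function(cnd) {
  if (inherits(cnd, "ws_validation_error")) return(2L)
  if (inherits(cnd, "ws_computation_error")) return(3L)
  if (inherits(cnd, "ws_degenerate_error")) return(4L)
  1L
}
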