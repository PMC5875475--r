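#' @keywords internal
#' @noRd
stop_ctssp <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ctssp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# input/configuration problems (bad paths, bad configs, malformed files)
stop_input <- function(msg) stop_ctssp(msg, "ctssp_input_error")

# computation problems (degenerate signals, failed fits, truncated profiles)
stop_compute <- function(msg, class = NULL) {
  stop_ctssp(msg, c(class, "ctssp_compute_error"))
}

warn_ctssp <- function(msg, class) {
  warning(structure(
    class = c(class, "ctssp_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
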