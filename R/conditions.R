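#' @keywords internal
#' @noRd
abort_chick <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "chickcall_error"),
                      call = call))
}

#' @keywords internal
#' @noRd
warn_chick <- function(message, class) {
  warning(warningCondition(message, class = c(class, "chickcall_warning")))
}
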