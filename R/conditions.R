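#' @keywords internal
#' @noRd
mspe_abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mspe_error")))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
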