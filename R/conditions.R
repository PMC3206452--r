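# Structured condition helpers.  Every user-facing failure in the package is
# signalled with a classed condition so callers (and the batch CLI) can react
# per failure mode instead of string-matching messages.

qc_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "qc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

qc_warn <- function(message, class, ...) {
  warning(structure(
    class = c(class, "qc_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
qc_log <- local({
  enabled <- FALSE
  function(msg = NULL, enable = NULL) {
    if (!is.null(enable)) {
      enabled <<- isTRUE(enable)
      return(invisible(enabled))
    }
    if (enabled && !is.null(msg)) message("[qchemlog] ", msg)
    invisible(NULL)
  }
})

#' Enable or disable diagnostic logging
#'
#' The engine and the transform interpreter are deliberately tolerant: a
#' template that claims no chunk or a transform whose path matches nothing is
#' a silent no-op.  With logging enabled each such event emits one structured
#' line, so it is auditable which sections of a logfile were parsed and which
#' were not.
#'
#' @param enable `TRUE` or `FALSE`.
#' @return The new setting, invisibly.
#' @export
qc_logging <- function(enable = TRUE) {
  qc_log(enable = enable)
}
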