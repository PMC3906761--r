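#' @name pharmaboost-conditions
#' @title Typed error conditions
#'
#' @description
#' All user-facing errors raised by pharmaboost carry one of four condition
#' classes so that callers (including the bundled command-line script) can map
#' failures to distinct exit codes:
#' \describe{
#'   \item{`pb_validation_error`}{invalid arguments, configs or inconsistent
#'     user inputs (exit code 2)}
#'   \item{`pb_format_error`}{malformed input files; the message names the
#'     offending file and, where known, the line (exit code 3)}
#'   \item{`pb_config_error`}{unknown dialects, levels or methods (exit code 2)}
#'   \item{`pb_internal_error`}{internal-consistency failures such as a
#'     negative contingency cell (exit code 4)}
#' }
NULL

pb_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "pb_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

pb_validation_error <- function(message, ...) pb_stop("pb_validation_error", message, ...)
pb_config_error     <- function(message, ...) pb_stop("pb_config_error", message, ...)
pb_internal_error   <- function(message, ...) pb_stop("pb_internal_error", message, ...)

pb_format_error <- function(message, file = NULL, line = NULL) {
  loc <- ""
  if (!is.null(file)) loc <- paste0(" [file: ", file, if (!is.null(line)) paste0(", line ", line), "]")
  pb_stop("pb_format_error", paste0(message, loc), file = file, line = line)
}

#' Map a pharmaboost condition to a process exit code
#'
#' @param cond a condition object.
#' @return Integer exit code: 2 (validation/configuration), 3 (format),
#'   4 (internal consistency), 1 for any other error.
#' @export
pb_exit_code <- function(cond) {
  if (inherits(cond, "pb_format_error")) return(3L)
  if (inherits(cond, "pb_internal_error")) return(4L)
  if (inherits(cond, c("pb_validation_error", "pb_config_error"))) return(2L)
  1L
}
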