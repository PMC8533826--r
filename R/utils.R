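#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Task labels recognised throughout the package
#'
#' @return Character vector of valid task codes.
#' @export
sms_tasks <- function() {
  c("sms", "unpaced_comfortable", "unpaced_fast",
    "paced_300", "paced_600", "monitoring")
}

# Signal a recoverable "not enough data" state. Callers receive NA-valued
# results plus a classed warning so pipelines can count the dropouts.
insufficient_data <- function(msg) {
  warning(warningCondition(msg, class = "speechsync_insufficient_data"))
}

# A feature that cannot be measured on this input propagates as NA (never
# 0) so downstream models drop it explicitly.
undefined_feature <- function(msg) {
  warning(warningCondition(msg, class = "speechsync_undefined_feature"))
  NA_real_
}

# Classed errors keep the distinction between malformed files (format),
# invalid values (validation) and bad parameters visible to callers.
stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("speechsync_format_error", "error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("speechsync_validation_error", "error")))
}

stop_parameter <- function(msg) {
  stop(errorCondition(msg, class = c("speechsync_parameter_error", "error")))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_parameter(sprintf("`%s` must be a single number in [%s, %s]",
                           name, format(lower), format(upper)))
  }
  invisible(x)
}
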