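# Classed conditions so callers (and the orchestration layer) can tell
# malformed input files apart from invalid parameter values.

schema_error <- function(message, file = NULL, row = NULL, column = NULL,
                         call = sys.call(-1)) {
  loc <- c(
    if (!is.null(file)) paste0("file '", file, "'"),
    if (!is.null(row)) paste0("row ", row),
    if (!is.null(column)) paste0("column '", column, "'")
  )
  if (length(loc)) message <- paste0(message, " [", paste(loc, collapse = ", "), "]")
  stop(errorCondition(message, class = c("caco2_schema_error", "error"),
                      call = call))
}

validation_error <- function(message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c("caco2_validation_error", "error"),
                      call = call))
}

# stopifnot-style numeric check with a named message
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("'%s' must be a finite numeric scalar", name))
  ok_low <- if (allow_equal_lower) x >= lower else x > lower
  if (!ok_low || x > upper)
    validation_error(sprintf(
      "'%s' must be in %s%g, %g]; got %g", name,
      if (allow_equal_lower) "[" else "(", lower, upper, x))
  invisible(x)
}
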