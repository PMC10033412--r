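#' @title Categorized error conditions
#' @description Internal constructors for the package's structured error
#'   classes. Every validation failure raises exactly one of these, so callers
#'   can dispatch on `cs_schema_error` (a declared column is missing),
#'   `cs_parse_error` (a cell cannot be interpreted, reported with its row),
#'   `cs_integrity_error` (cross-field or cross-record inconsistency) or
#'   `cs_config_error` (an invalid argument or configuration value).
#' @name conditions
#' @keywords internal
NULL

csStop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cs_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

schemaError    <- function(msg) csStop("cs_schema_error", msg)
parseError     <- function(msg) csStop("cs_parse_error", msg)
integrityError <- function(msg) csStop("cs_integrity_error", msg)
configError    <- function(msg) csStop("cs_config_error", msg)

# Numeric coercion that names the offending row (1-based, excluding header)
parseNumeric <- function(x, column, file = "") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0L) {
    parseError(sprintf(
      "non-numeric value '%s' in column '%s'%s (row %d)",
      x[bad[1L]], column, if (nzchar(file)) paste0(" of ", file) else "", bad[1L]
    ))
  }
  out[!is.na(x) & x == ""] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
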