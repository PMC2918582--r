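# Conditioned aborts carrying machine-readable codes (E_DOMAIN, E_RANGE, ...).
# Condition classes are "s3db_e_<lowercase code>" plus "s3db_error".

s3db_abort <- function(code, message, ...) {
  rlang::abort(
    message,
    class = c(paste0("s3db_", tolower(code)), "s3db_error"),
    code = code,
    ...
  )
}

#' Extract the machine-readable code from an s3db error condition
#'
#' Validation and usage errors raised by the package carry a stable code
#' (`E_DOMAIN`, `E_RANGE`, `E_MEMBERSHIP`, `E_OBJECT_TYPE`, `E_DUP_ROOT`,
#' `E_EDIT_UNSUPPORTED`, ...) so that callers can dispatch without parsing
#' messages.
#'
#' @param cnd A condition object caught from an s3db function.
#' @return The code as a string, or `NA_character_` for foreign conditions.
#' @export
s3db_error_code <- function(cnd) {
  code <- cnd$code
  if (is.null(code)) NA_character_ else code
}
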