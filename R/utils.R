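# Shared internal helpers.

# User-facing error: CLI maps these to exit status 1, everything else to 2.
stop_user <- function(fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("ucscdb_user_error", "ucscdb_error")))
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_whole <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x) && x == trunc(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
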