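# internal helpers shared across modules

# stop with a consistent error header; `where` names the offending
# row/column so validation failures are actionable
abort_validation <- function(msg, where = NULL) {
  if (!is.null(where)) msg <- paste0(msg, " [", where, "]")
  stop(msg, call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# canonical numeric formatting used by all writers so that one
# write -> read -> write round trip is byte-stable
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else as.character(v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
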