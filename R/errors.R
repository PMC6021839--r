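#' @keywords internal
ts_error <- function(code, msg, call = sys.call(-1)) {
  stop(errorCondition(
    sprintf("[%s] %s", code, msg),
    code = code,
    class = c(paste0("touchsplit_error_", code), "touchsplit_error", "error", "condition"),
    call = call
  ))
}

#' Signal that the box-based route cannot cut this blob
#'
#' `FALLBACK` is a typed value, not an error: the box route hands the blob
#' over to the shape route, exactly as the controller expects.
#'
#' @param reason short machine-readable string.
#' @return An object of class `touchsplit_fallback`.
#' @export
fallback <- function(reason = "unspecified") {
  structure(list(reason = reason), class = "touchsplit_fallback")
}

#' Test for the fallback signal
#' @param x any object.
#' @return `TRUE` if `x` was produced by [fallback()].
#' @export
is_fallback <- function(x) inherits(x, "touchsplit_fallback")

#' @export
print.touchsplit_fallback <- function(x, ...) {
  cat("<fallback to shape route:", x$reason, ">\n")
  invisible(x)
}

## tiny FNV-1a, used only to fingerprint configurations in reports
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte (b < 256); keep everything in doubles
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    ## 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
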