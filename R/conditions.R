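# Classed conditions so callers (and the CLI) can dispatch on failure mode.
# All error classes inherit "spotglyphs_error"; warnings, "spotglyphs_warning".

sgStop <- function(subclass, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(subclass, "spotglyphs_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

sgWarn <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "spotglyphs_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  )
  warning(cond)
}

# shorthand for "a, b, c" lists in messages, truncated when long
sgOxford <- function(x, max = 10L) {
  x <- as.character(x)
  if (length(x) > max) {
    x <- c(x[seq_len(max)], sprintf("... (%d more)", length(x) - max))
  }
  paste(x, collapse = ", ")
}
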