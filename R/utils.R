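# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers and tests can distinguish failure modes
# without matching message text.
dd_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "dnadesign_error", "error")))
}

dd_warn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "dnadesign_warning", "warning")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
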