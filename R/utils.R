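# Internal helpers shared across modules.

# Round half away from zero. Reported chronologies are integer days and must not
# depend on IEEE round-half-to-even (base round()); 0.5 always rounds up.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Condition constructor: all package errors carry a subclass so callers (and
# tests) can dispatch on the failure mode rather than on message text.
tc_stop <- function(subclass, message, call. = FALSE) {
  stop(structure(
    class = c(subclass, "toothchron_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_flag <- function(x) {
  is.logical(x) && length(x) == 1L && !is.na(x)
}
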