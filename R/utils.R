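# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sepsafe <- function(..., class = "sepsafe_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_count <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop_sepsafe(name, " must be a single ",
                 if (positive) "positive" else "non-negative", " integer",
                 class = "sepsafe_config_error")
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_sepsafe(name, " must lie in [0, 1]", class = "sepsafe_config_error")
  }
  x
}

# Apply a comparator given as a string ("<", "<=", ">", ">=", "==") to a
# numeric vector; used by the hazard predicates so scenario definitions
# stay serializable as plain text.
apply_comparator <- function(x, op, threshold) {
  switch(op,
    "<"  = x < threshold,
    "<=" = x <= threshold,
    ">"  = x > threshold,
    ">=" = x >= threshold,
    "==" = x == threshold,
    stop_sepsafe("unknown comparator '", op, "'")
  )
}

clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Derive a stage seed from a master seed; keeps every stochastic stage
# independently seeded while the whole run is reproducible from one integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483647)
}
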