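# Internal helpers shared across modules.

# Classed error so callers can branch on failure modes.
es_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "eventseg_error", "error", "condition")))
}

# All diagnostic logging funnels through here so tests can capture it.
es_log <- function(...) {
  message("eventseg: ", ...)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# NULL seed means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Integer-valued check tolerant of doubles coming from CSV round trips.
is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    es_error(sprintf("%s must be a single non-missing string", what),
             "eventseg_invalid_input")
  }
  invisible(x)
}
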