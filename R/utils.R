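# Internal helpers shared across the package.

# Classed error, so callers and tests can match on condition class rather
# than message text.
stop_rp <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "rp_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

warn_rp <- function(class, msg) {
  warning(structure(
    class = c(class, "rp_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. Generator kind is pinned so seeded fixtures are part of
# the public contract.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  expr
}
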