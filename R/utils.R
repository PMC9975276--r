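# internal helpers: classed error conditions and seeded random generation

stop_ftsz <- function(class, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "ftszdyn_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ftsz("ftszdyn_invalid_argument",
              sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_ftsz("ftszdyn_invalid_argument",
              sprintf("`%s` must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_ftsz("ftszdyn_invalid_argument",
              sprintf("`%s` must be >= 0 (got %g)", name, x))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generator randomness flows through this so that identical seeds give
# bit-identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

check_strictly_increasing <- function(time, name = "time") {
  if (length(time) < 2L || any(diff(time) <= 0))
    stop_ftsz("ftszdyn_invalid_argument",
              sprintf("`%s` must be strictly increasing", name))
  invisible(time)
}
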