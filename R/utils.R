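# internal helpers shared across modules

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All user-facing randomness in the package flows through explicit seeds.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be coercible to integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(sprintf("'%s' must be a single finite positive number", name))
  invisible(as.numeric(x))
}
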