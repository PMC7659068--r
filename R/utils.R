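#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("`seed` must be coercible to an integer", call. = FALSE)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
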