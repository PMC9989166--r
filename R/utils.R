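#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop_invalid(sprintf("'%s' must be a numeric of length %d", name, len))
  lo_ok <- if (strict_min) all(x > min) else all(x >= min)
  if (!lo_ok || !all(x <= max))
    stop_invalid(sprintf("'%s' out of range [%s, %s]%s", name,
                         format(min), format(max),
                         if (strict_min) " (strictly above lower bound)" else ""))
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid(sprintf("'%s' must be TRUE or FALSE", name))
  x
}

# Fan a user-facing seed out to per-stage seeds with fixed offsets, staying
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
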