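# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a fixed RNG seed, restoring any pre-existing global
# RNG state afterwards: no hidden global random state leaks out.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_scalar_num(x))
    stopf("invalid-parameter: `%s` must be a finite numeric scalar", name)
  ok <- if (strict_lower) x > lower else x >= lower
  ok <- ok && if (strict_upper) x < upper else x <= upper
  if (!ok)
    stopf("invalid-parameter: `%s` = %g outside its valid range", name, x)
  invisible(x)
}
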