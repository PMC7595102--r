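# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-padded feature ids: feature_ids("G", 3, 10000) -> "G00003"
feature_ids <- function(prefix, i, n) {
  sprintf("%s%0*d", prefix, max(5L, nchar(as.character(n))), i)
}

stop2 <- function(...) stop(..., call. = FALSE)
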