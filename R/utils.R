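# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards; seed = NULL uses the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed, stable and < 2^31
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
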