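# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. With seed = NULL the code runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ordering_key <- function(ord) paste(ord, collapse = ",")

check_ordering <- function(order, p) {
  order <- as.integer(order)
  if (length(order) != p || anyNA(order) || !setequal(order, seq_len(p)))
    stop("'order' must be a permutation of 1..", p)
  order
}
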