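# internal helpers shared across the package

# weights are carried as numerics but all objective arithmetic is done on
# integer-scaled copies (6 decimal places) so lexicographic comparisons never
# hit floating-point ties
.WSCALE <- 1e6L

.scale_weight <- function(w) round(w * as.numeric(.WSCALE))

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# strict lexicographic comparison of integer-scaled objective triples:
# -1 if a < b, 0 if equal, 1 if a > b
.lex_cmp <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

.flip_sign <- function(x) ifelse(x == "up", "down", "up")
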