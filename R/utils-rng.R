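# Local, restorable RNG handling so every stochastic operation is
# reproducible from an explicit seed without disturbing the caller's stream.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a distinct 31-bit sub-seed from a base seed and integer tags
# (year index, layer index, repeat number, ...). Deterministic, collision
# free for the small tag ranges used here.
sub_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) s <- (s * 48271 + as.double(t) + 1) %% 2147483647
  as.integer(s)
}
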