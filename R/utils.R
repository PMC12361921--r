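# evaluate expr with a locally set RNG seed, restoring the caller's RNG
# state afterwards; seed = NULL leaves the RNG untouched
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derive a stream of child seeds from one parent seed (all < 2^31)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed_(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}
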