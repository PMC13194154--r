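# Local seeding: every stochastic operation in the package takes an explicit
# seed and runs under it without disturbing the caller's RNG stream.
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a per-item seed from a base seed; kept below 2^31 - 1
derive_seed <- function(seed, index) {
  (as.integer(seed) + 1000003L * as.integer(index)) %% .Machine$integer.max
}
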