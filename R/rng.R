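# Seed handling: every stochastic operation takes an explicit seed and runs
# inside with_seed(), which restores the caller's RNG state afterwards, so no
# function leaks changes to the global stream.

with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic sub-seed derived from a master seed and a sequence of keys
# (numbers or strings). A linear-congruential fold keeps everything exact in
# double precision and below 2^31, so independent stages of a pipeline get
# separated streams from one user-facing seed.
child_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483629
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = "|")))
    for (v in as.double(k)) {
      h <- (h * 69069 + (v %% 2147483629) + 1) %% 2147483629
    }
  }
  as.integer(h %% 2147483629) + 1L
}
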