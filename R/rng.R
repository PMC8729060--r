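# Reproducible substreams: one master seed spawns named streams so that the
# draws for one purpose (latent BC hazard, other-cause death, each adverse
# event) never depend on whether another purpose was sampled, and draws are
# indexed by woman id so extending a cohort leaves earlier ids untouched.

# djb2-style string hash folded with the master seed; all arithmetic stays
# below 2^53 so it is exact in doubles, and the result fits a 32-bit seed.
substream_seed <- function(master_seed, purpose) {
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(as.character(purpose))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a purpose-keyed seed, restoring the caller's RNG state.
with_substream <- function(master_seed, purpose, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(substream_seed(master_seed, purpose))
  expr
}

substream_runif <- function(master_seed, purpose, n) {
  with_substream(master_seed, purpose, runif(n))
}
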