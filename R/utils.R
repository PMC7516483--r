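# Save/restore the global RNG state so seeded routines leave no trace.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's
# RNG stream.
.with_seed <- function(seed, code) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed %% .Machine$integer.max)
  force(code)
}
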