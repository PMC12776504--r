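# Set a local seed and restore the caller's RNG stream when the calling
# function exits. Internal functions that take explicit seed arguments use
# this, so that e.g. permutation loops around loocv_evaluate() keep drawing
# fresh permutations from the ambient stream.
local_seed <- function(seed, envir = parent.frame()) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  do.call(on.exit, list(quote({
    if (!is.null(.pdcnet_old_seed))
      assign(".Random.seed", .pdcnet_old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }), add = TRUE), envir = envir)
  assign(".pdcnet_old_seed", old, envir = envir)
  set.seed(as.integer(seed))
}
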