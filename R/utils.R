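# Internal helpers.

# Scoped RNG: seed the generator for the duration of the calling function and
# restore the previous global RNG state on exit, so no simulator call leaks
# random state.
local_rng <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  restore <- if (is.null(old)) {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }
  } else {
    function() assign(".Random.seed", old, envir = globalenv())
  }
  withr::defer(restore(), envir = env)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Stable hash of an R object (used to stamp pipeline outputs): serialize to a
# temporary file and md5 it. Path-like fields (out_dir) are excluded by the
# caller so that the same scientific configuration hashes identically
# wherever its outputs land.
config_hash <- function(x) {
  if (is.list(x)) x <- x[setdiff(names(x), "out_dir")]
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
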