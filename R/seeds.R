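#' Derive a reproducible sub-seed from a master seed and a text tag
#'
#' Named independent random streams (initial strategies per layer, link
#' assignment, update sequences, sweep cells) are all derived from one master
#' seed by mixing it with a short tag through a splitmix64 hash. The result is
#' an integer-valued double below 2^31, usable both as an R seed and as a
#' stream seed for the compiled engine.
#'
#' @param seed integer master seed
#' @param tag character tag naming the stream
#' @return integer-valued double in `[0, 2^31)`
#' @export
#' @examples
#' derive_seed(1, "links")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  cpp_hash_seed(as.double(seed), paste(tag, collapse = "|"))
}

# Evaluate expr with R's RNG seeded locally, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
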