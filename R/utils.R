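# RNG plumbing shared by the generators and the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so seeded
#' generators are pure functions of (config, seed).
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic child seed from a parent seed
#'
#' One global seed fans out to per-stage child seeds; all seeds stay below
#' 2^31.
#' @param seed parent integer seed.
#' @param k stage index (>= 1).
#' @return integer child seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 12345 * as.double(k)) %% 2147483587)
}
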