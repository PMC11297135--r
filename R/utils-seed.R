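#' Derive a child seed from a master seed and a label
#'
#' Deterministic fan-out of one master seed to the pipeline stages (world
#' generation, train/test split, per-member initialization) so that a single
#' integer reproduces an entire run. The derivation is a polynomial rolling
#' hash of the label folded into the master seed, reduced modulo 2^31 - 1 so
#' the result is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param label character label of the consumer (e.g. "split", "member-3").
#' @return a single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(as.character(label))) {
    # h <- (h * 131 + code) mod m, kept in double-safe range (< 2^51)
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded internals do not
#' perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
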