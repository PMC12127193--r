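# Internal helpers shared across modules.

.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Stage seeds are a deterministic affine hash of the master seed and a stage
#' index, reduced modulo 2^31 - 1 so the result is a valid 32-bit integer
#' seed. Each pipeline stage draws from its own stream, so toggling one stage
#' never shifts the randomness of another.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed.
#' @export
#' @examples
#' split_seed(1, 0)
#' split_seed(1, 3)
split_seed <- function(master, stage) {
  .assert(is.numeric(master) && length(master) == 1 && is.finite(master),
          "master seed must be a single finite number")
  .assert(is.numeric(stage) && length(stage) == 1 && stage >= 0,
          "stage index must be a single non-negative number")
  as.integer((abs(as.double(master)) * 7919 + 104729 * (as.double(stage) + 1)) %%
               2147483647)
}
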