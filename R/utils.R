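# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed from a master seed
#'
#' All stochastic steps (archetype placement, depth sampling, read placement,
#' weight initialization, minibatch shuffling, latent sampling, clustering
#' tie-breaks) draw from sub-streams derived from one master seed, so a single
#' integer reproduces an entire pipeline run.
#'
#' @param seed master seed (integer).
#' @param stream sub-stream index (non-negative integer).
#' @return an integer seed below 2^31.
#' @keywords internal
child_seed <- function(seed, stream) {
  # affine map modulo a Mersenne prime; keeps values in 32-bit integer range
  as.integer((as.double(seed) * 2654435761 + 97 * as.double(stream) + 1) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
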