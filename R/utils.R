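#' Derive a reproducible stage or substream seed
#'
#' All randomness in the package flows from one master seed.  Stage seeds and
#' per-patient substream seeds are derived deterministically from the master
#' seed and a label, so that stages can be rerun independently and the result
#' of generating patient k never depends on how many patients were generated
#' before it.
#'
#' @param seed master seed (integer).
#' @param label character label naming the stage or substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, "simulate")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # 32-bit FNV-1a style mix over the label bytes, folded with the seed
  h <- (abs(seed) %% 2147483647)
  for (b in utf8ToInt(paste(label, collapse = ""))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Run code under a temporary RNG state; restores .Random.seed afterwards so
# package functions never perturb the caller's stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the length-1 surprise
sample_exact <- function(x, size) x[sample.int(length(x), size)]
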