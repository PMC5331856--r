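#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named seed substream from a master seed
#'
#' All randomness in a run flows from one master seed through named
#' substreams (`"stimulus"`, `"subjects"`, `"noise"`, ...), optionally
#' indexed, so stages can be re-seeded independently and reproducibly.
#' The derived seed is a deterministic 31-bit hash, safe as an R integer.
#'
#' @param master Master integer seed.
#' @param label Substream name.
#' @param index Optional integer index (e.g. subject or block number).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(master, label, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master) %% m)
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  # one multiplicative scramble (Lehmer step) to decorrelate nearby indices
  h <- (h * 48271) %% m
  as.integer(h) + 1L
}
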