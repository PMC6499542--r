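# Internal helpers shared across modules.

#' Index unordered population pairs
#'
#' Pairs are enumerated in `combn` order: (1,2), (1,3), ..., (1,P), (2,3), ...
#' All pairwise structures in the package (fold-change matrices,
#' differentiation matrices) use this ordering.
#'
#' @param populations Character vector of population labels.
#' @return A list with integer vectors `i`, `j` (first/second member of each
#'   pair), `labels` ("popA|popB"), and `n_pairs`.
#' @keywords internal
pair_index <- function(populations) {
  p <- length(populations)
  if (p < 2L) stop("need at least 2 populations", call. = FALSE)
  cmb <- utils::combn(p, 2L)
  list(
    i = cmb[1L, ],
    j = cmb[2L, ],
    labels = paste(populations[cmb[1L, ]], populations[cmb[2L, ]], sep = "|"),
    n_pairs = ncol(cmb)
  )
}

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the simulators flows from one user seed; each logical
#' stream (expression means, counts, library sizes, ...) draws from a
#' deterministic sub-seed so components can be regenerated independently.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name.
#' @return Integer in [0, 2^31 - 2].
#' @keywords internal
stream_seed <- function(seed, stream) {
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Evaluate expr under a named stream seed, restoring RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# log2(x + 1), the log transform used throughout for expression comparisons
log2p1 <- function(x) log2(x + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
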