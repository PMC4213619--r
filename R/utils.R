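#' Derive a reproducible integer sub-seed from a master seed
#'
#' Mixes a master seed with a sequence of integer indices (e.g. trait, tree,
#' map number) into a deterministic seed below 2^31, so that independent units
#' of work (one stochastic map, one tree) each get their own RNG substream.
#' Running units in any order, or in parallel, then reproduces the serial
#' result exactly.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the unit of work.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 3, 1, 7)
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  # multiplicative Lehmer step per index; doubles stay below 2^53
  for (i in idx) {
    s <- (s * 48271 + (as.double(i) + 1) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

# evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards; with seed = NULL uses the ambient stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cultrates <- function(msg, class) {
  stop(structure(class = c(class, "cultrates_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
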