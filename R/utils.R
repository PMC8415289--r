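#' Derive a reproducible child seed from a master seed and a stream name
#'
#' Analysis stages (Fs null simulations, PhiST permutations, ABC reference
#' tables, ...) each draw from their own named stream so that re-running one
#' stage never perturbs another. The child seed is a deterministic hash of
#' the master seed and the stream label, kept within the 32-bit integer
#' range R requires of `set.seed()`.
#'
#' @param seed integer master seed
#' @param stream character stream label
#' @return an integer seed
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) guarding against underflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
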