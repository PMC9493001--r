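#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded generators do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed (must be < 2^31).
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic substream seed
#'
#' All randomness in the cohort generator flows from one root seed through
#' this map, so any (patient, side, purpose) unit can be regenerated in
#' isolation and in any order. The result is kept below 2^31 - 1.
#'
#' @param root root integer seed.
#' @param ... further integer components (patient index, side index, stream
#'   tag).
#' @return a positive integer seed.
#' @keywords internal
substream_seed <- function(root, ...) {
  parts <- c(as.numeric(root), as.numeric(unlist(list(...))))
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- 0
  for (p in parts) h <- (h * 48271 + (p %% m) + 1) %% m
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
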