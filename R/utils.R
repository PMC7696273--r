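#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's random stream. With `seed = NULL` the expression is
#' evaluated against the current stream (no isolation).
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a base seed and a stream index
#'
#' Deterministic, collision-poor mapping kept strictly below 2^31 so the
#' result is a valid R integer seed.
#'
#' @param seed Base integer seed.
#' @param ... One or more non-negative integer stream indices.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

abort_arg <- function(...) stop(..., call. = FALSE)

#' First temporal difference with the first element set to zero
#' @param x Numeric vector or matrix (differenced along rows).
#' @keywords internal
temporal_derivative <- function(x) {
  if (is.matrix(x)) rbind(0, diff(x)) else c(0, diff(x))
}

# FNV-1a 32-bit hash of a character scalar; used for config provenance tags.
# Arithmetic is done on 16-bit halves so every intermediate stays exact in
# double precision.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # XOR of low byte only (b < 256): split h into low byte and rest
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply mod 2^32 via 16-bit split
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
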