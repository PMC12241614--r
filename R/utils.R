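#' Derive reproducible sub-stream seeds from a root seed
#'
#' Every stochastic component of the package draws its own seed from the root
#' seed through a fixed Lehmer (multiplicative congruential) recurrence, so
#' that components can be re-run independently and the derivation order is
#' documented and stable. All derived seeds lie in `[1, 2^31 - 2]`.
#'
#' @param seed Integer root seed.
#' @param n Number of derived seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  r <- (abs(as.double(seed)) %% 2147483646) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- (r * 48271) %% 2147483647
    out[i] <- r
  }
  as.integer(out)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG state is restored on exit.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stop with a message naming the offending field.
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

# Named list -> data.frame row counts etc. kept minimal on purpose.
`%||%` <- function(a, b) if (is.null(a)) b else a
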