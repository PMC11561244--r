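#' Split one seed into deterministic child seeds
#'
#' All stochastic stages of the package take a single integer seed; stages
#' with several independent random streams (imputation chains, replicate
#' simulations) derive child seeds from it so that no stream ever reuses
#' another's random numbers.
#'
#' @param seed integer scalar.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
splitSeed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Weyl-style sequence on the 31-bit ring; avoids consuming the global RNG.
  s <- (as.double(seed) %% 2147483647) + 1
  phi <- 1327217885  # odd multiplier coprime with 2^31 - 1
  as.integer(1 + (s * 69069 + phi * seq_len(n)) %% 2147483645)
}

.assert_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) ||
      any(x > if (allow_one) 1 else 1 - .Machine$double.eps)) {
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Evaluate expr with the global RNG seeded, restoring prior RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
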