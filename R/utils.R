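# Internal helpers: classed error conditions and seed discipline.

imb_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "imbfuse_error"),
                      call = call))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so that seeded package internals never disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old_seed <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old_seed, envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a master seed
#'
#' One integer master seed drives every stochastic stage (fold construction,
#' subspace draws, SMOTE, the genetic algorithm). Child seeds are obtained by
#' folding stream identifiers into the master seed with a fixed linear
#' congruential step, keeping the result in (0, 2^31 - 1). The scheme is a
#' documented convention, not a cryptographic one: its only job is to make
#' every stage reproducible from a single number while keeping streams for
#' different stages distinct.
#'
#' @param seed Integer master seed.
#' @param ... Integer stream identifiers (e.g. run index, fold index, stage
#'   code), folded in order.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  ids <- as.double(c(...))
  s <- as.double(seed) %% 2147483647
  for (id in ids) {
    s <- (s * 69069 + id * 12345 + 1) %% 2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# squared Euclidean distances between rows of a and rows of b (dense, exact)
pairwise_sqdist <- function(a, b = a) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
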