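#' Numerically stable row-wise softmax
#'
#' @param x numeric matrix; each row is one score vector.
#' @return matrix of the same shape with non-negative rows summing to 1.
#' @keywords internal
row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x, alpha = 1) ifelse(x > 0, x, alpha * (exp(x) - 1))

elu_grad <- function(x, alpha = 1) ifelse(x > 0, 1, alpha * exp(x))

relu <- function(x) pmax(x, 0)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that generation is a pure
#' function of the supplied seed.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range so they remain valid
#' arguments to [set.seed()].
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
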