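# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded generators behave as pure functions of
#' their configuration.  With `seed = NULL` the expression just uses the
#' current stream.
#'
#' @param seed integer scalar or NULL
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed for a named stage, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset) * 10007L) %% .Machine$integer.max
}

#' Draw from a Dirichlet distribution
#'
#' @param n number of draws
#' @param alpha positive concentration vector
#' @return n x length(alpha) matrix of simplex rows
#' @keywords internal
#' @noRd
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Inverse digamma function
#'
#' Newton iteration after the standard asymptotic initialiser; accurate to
#' ~1e-12 over the range needed for Dirichlet estimation.  Vectorised.
#'
#' @keywords internal
#' @noRd
inv_digamma <- function(y) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y + 0.5772156649015329))
  for (i in 1:8) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
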