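#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so seeded package functions are
#' pure functions of their arguments and never disturb the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a master seed and a stage label; stays < 2^31.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

## Trapezoidal integral of y over x (both numeric, x strictly ascending).
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, all(diff(x) > 0))
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

## Linear-interpolation percentile (quantile type 7), the convention used for
## hub cut-offs.
pctile <- function(x, p) unname(stats::quantile(x, p / 100, type = 7, names = FALSE))

## Check a square matrix is symmetric within tolerance.
isSymmetricMat <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

## Upper-triangle index pairs (i < j) of an n x n matrix, row-major order.
upperPairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

## Row-major linear index into the upper triangle for stable tie-breaking.
upperOrderIndex <- function(n) {
  up <- upperPairs(n)
  (up[, "i"] - 1L) * n + up[, "j"]
}

#' @importFrom utils head tail
NULL
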