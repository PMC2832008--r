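#' @importFrom stats rnorm runif rgamma rmultinom median sd prcomp hclust
#'   cutree as.dist dist cor pt dhyper setNames aggregate quantile
#' @importFrom utils read.delim write.table packageVersion
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

logSumExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Optimal one-to-one assignment maximising sum of scores, exact bitmask DP.
# score: n x n matrix (rows = clusters, cols = templates). Returns the column
# assigned to each row. n is small (<= 12).
bestAssignment <- function(score) {
  n <- nrow(score)
  stopifnot(ncol(score) == n, n <= 12L)
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(-Inf, full + 1L)
  choice <- vector("list", full + 1L)
  best[1L] <- 0
  for (mask in 0:(full - 1L)) {
    if (!is.finite(best[mask + 1L])) next
    row <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L) + 1L
    for (col in seq_len(n)) {
      bit <- bitwShiftL(1L, col - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      nm <- bitwOr(mask, bit)
      val <- best[mask + 1L] + score[row, col]
      if (val > best[nm + 1L]) {
        best[nm + 1L] <- val
        choice[[nm + 1L]] <- c(choice[[mask + 1L]], col)
      }
    }
  }
  choice[[full + 1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
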