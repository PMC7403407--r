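#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' restoring the previous RNG state afterwards, so that seeded package
#' functions are pure functions of (inputs, seed) and do not disturb the
#' caller's random stream. With `seed = NULL` the code runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# coerce dist or matrix input to a validated square symmetric matrix
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("expected a square distance matrix or 'dist' object")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  d
}

# lower-triangle vector of a square matrix
lower_tri <- function(m) m[lower.tri(m)]

# permutation p-value, (b + 1) / (m + 1) estimator
perm_p <- function(perm_stats, observed, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  b <- if (alternative == "greater") {
    sum(perm_stats >= observed - 1e-12)
  } else {
    sum(perm_stats <= observed + 1e-12)
  }
  (b + 1) / (length(perm_stats) + 1)
}

# pool-adjacent-violators: least-squares monotone (non-decreasing) fit,
# unit weights; returns the fitted vector
pava <- function(y) {
  n <- length(y)
  if (n == 0L) return(y)
  val <- numeric(n)   # block values
  w <- numeric(n)     # block weights
  len <- integer(n)   # block lengths
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; w[nb] <- 1; len[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      val[nb - 1L] <- (w[nb - 1L] * val[nb - 1L] + w[nb] * val[nb]) /
        (w[nb - 1L] + w[nb])
      w[nb - 1L] <- w[nb - 1L] + w[nb]
      len[nb - 1L] <- len[nb - 1L] + len[nb]
      nb <- nb - 1L
    }
  }
  rep(val[seq_len(nb)], len[seq_len(nb)])
}
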