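# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Spin a derived stage seed off a master seed, staying inside 32-bit range.
deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rank() along rows of a matrix, average ties (Spearman convention).
rowRanks <- function(m) {
  t(apply(m, 1L, rank, ties.method = "average"))
}

# Pairwise Spearman rho for selected (i, j) row pairs of an abundance
# matrix, computed over a subset of columns. Returns NA where either row is
# constant on those columns.
spearmanPairs <- function(m, pairs, cols = seq_len(ncol(m))) {
  sub <- m[, cols, drop = FALSE]
  nk <- ncol(sub)
  r <- rowRanks(sub)
  mu <- rowMeans(r)
  s <- sqrt(rowSums((r - mu)^2) / (nk - 1))
  z <- (r - mu) / ifelse(s > 0, s, NA_real_)
  rowSums(z[pairs[, 1L], , drop = FALSE] * z[pairs[, 2L], , drop = FALSE]) /
    (nk - 1)
}

stopIfNot <- function(cond, ...) if (!cond) stop(sprintf(...), call. = FALSE)
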