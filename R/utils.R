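# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. All stochastic entry points funnel through this so
# a single integer seed makes a whole pipeline run reproducible.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Nearest-neighbour distances from each row of `a` to the point set `b`
# (both n x d, world mm). Exact; uses the |a|^2 + |b|^2 - 2ab expansion with
# BLAS and chunking so memory stays bounded.
nn_dist <- function(a, b, chunk = 2000L) {
  a <- as.matrix(a); b <- as.matrix(b)
  nb2 <- rowSums(b * b)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    ai <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ai * ai), nb2, "+") - 2 * tcrossprod(ai, b)
    idx <- max.col(-d2, ties.method = "first")
    out[i:j] <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), idx)], 0))
    i <- j + 1L
  }
  out
}

# Gaussian kernel used to weight profile offsets, K(d) = exp(-d^2 / (2 bw^2)).
gauss_kernel <- function(d, bandwidth) exp(-(d * d) / (2 * bandwidth * bandwidth))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
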