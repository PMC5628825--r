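# Sparse shape coding: the prior shapes themselves are the dictionary atoms.
#
# A new surface is expressed as a sparse weighted combination of training
# shapes; the weights are found from a handful of landmark observations by
# greedy orthogonal pursuit against the landmark sub-dictionary, jointly with
# a similarity transform carrying the observation into the aligned model
# frame. An optional sparse error vector absorbs grossly mis-placed
# landmarks.

#' Build the shape and landmark dictionaries from an aligned family
#'
#' Column `j` of `D_S` is shape `j` flattened vertex-major with xyz contiguous
#' per vertex: `(x1, y1, z1, x2, y2, z2, ...)`. `D_L` is the row restriction
#' of `D_S` to the landmark vertices, in landmark order. Atoms are kept in mm
#' (not unit-normalized): reconstructions must live in world units; pursuit
#' normalizes internally.
#'
#' @param aligned_shapes list of [corr_shape()]s in a common (GPA) frame with
#'   equal vertex counts.
#' @param landmark_indices integer vector of landmark vertex indices (1-based),
#'   optionally named by landmark group.
#' @return object of class `shape_dictionary`: `D_S` (3n x k), `D_L` (3l x k),
#'   `landmark_indices`, `atom_norms`, `n`, `k`, `faces`, `family_id`.
#' @export
build_dictionaries <- function(aligned_shapes, landmark_indices) {
  if (!length(aligned_shapes)) stopf("no shapes given")
  ns <- vapply(aligned_shapes, function(s) nrow(s$vertices), 1L)
  if (length(unique(ns)) != 1L) stopf("inconsistent vertex counts across shapes")
  n <- ns[1]
  landmark_indices <- as.integer(landmark_indices)
  if (any(landmark_indices < 1L) || any(landmark_indices > n))
    stopf("landmark index out of range 1..%d", n)
  ds <- vapply(aligned_shapes, function(s) as.numeric(t(s$vertices)),
               numeric(3L * n))
  ds <- matrix(ds, nrow = 3L * n)
  rows <- as.vector(t(outer(landmark_indices, 1:3,
                            function(j, c) 3L * (j - 1L) + c)))
  structure(list(
    D_S = ds, D_L = ds[rows, , drop = FALSE],
    landmark_indices = landmark_indices,
    landmark_rows = rows,
    atom_norms = sqrt(colSums(ds^2)),
    n = n, k = ncol(ds),
    faces = aligned_shapes[[1]]$faces,
    family_id = aligned_shapes[[1]]$family_id),
    class = "shape_dictionary")
}

#' @export
print.shape_dictionary <- function(x, ...) {
  cat(sprintf("<shape_dictionary> %d atoms, %d vertices (%d landmark rows)\n",
              x$k, x$n, length(x$landmark_rows)))
  invisible(x)
}

# Batch orthogonal matching pursuit against a fixed dictionary.
# Y: p x m observations; D: p x k atoms (any norms). Pursues up to k1 atoms
# per column, stopping early when the residual norm drops below tol.
# Returns k x m coefficient matrix (on the original atom scale) and residual
# norms. Gram-based so per-step work is in k-dim space.
omp_pursuit <- function(D, Y, k1, tol = 1e-12) {
  D <- as.matrix(D); Y <- as.matrix(Y)
  norms <- sqrt(colSums(D^2))
  if (all(norms == 0)) stopf("zero dictionary")
  keep <- norms > 0
  Dn <- sweep(D[, keep, drop = FALSE], 2, norms[keep], "/")
  k1 <- min(k1, ncol(Dn), nrow(Dn))
  G <- crossprod(Dn)
  D0 <- crossprod(Dn, Y)          # k x m initial correlations
  y2 <- colSums(Y^2)
  kk <- ncol(Dn); m <- ncol(Y)
  X <- matrix(0, ncol(D), m)
  rnorm2 <- y2
  for (col in seq_len(m)) {
    dty <- D0[, col]
    sup <- integer(0)
    xs <- numeric(0)
    r2 <- y2[col]
    corr <- dty
    for (step in seq_len(k1)) {
      if (r2 <= tol^2) break
      j <- which.max(abs(corr))
      if (abs(corr[j]) < 1e-14) break
      if (j %in% sup) break
      sup <- c(sup, j)
      gss <- G[sup, sup, drop = FALSE]
      xs <- tryCatch(solve(gss, dty[sup]), error = function(e) {
        qr.solve(gss + diag(1e-12, length(sup)), dty[sup])
      })
      corr <- dty - G[, sup, drop = FALSE] %*% xs
      r2 <- max(y2[col] - sum(dty[sup] * xs), 0)
    }
    if (length(sup)) X[which(keep)[sup], col] <- xs
    rnorm2[col] <- r2
  }
  # rescale coefficients back to original atom norms
  X[keep, ] <- X[keep, , drop = FALSE] / norms[keep]
  list(X = X, residual = sqrt(pmax(rnorm2, 0)))
}

# Iterative soft-thresholding (ISTA) solver for the l1-relaxed objective
# ||y - D x||^2 + lambda1 ||x||_1. Used when method = "ista".
ista_solve <- function(D, y, lambda1, n_iter = 500L, tol = 1e-10) {
  Dn2 <- norm(D, "2")^2
  if (Dn2 == 0) stopf("zero dictionary")
  step <- 1 / (Dn2 * 1.01)
  x <- numeric(ncol(D))
  for (i in seq_len(n_iter)) {
    g <- crossprod(D, D %*% x - y)
    xn <- x - 2 * step * g
    xn <- sign(xn) * pmax(abs(xn) - lambda1 * step, 0)
    if (sqrt(sum((xn - x)^2)) < tol * (1 + sqrt(sum(x^2)))) { x <- xn; break }
    x <- xn
  }
  x
}

#' Sparse-code an observation against a dictionary
#'
#' Greedy orthogonal pursuit under the `||x||_0 <= k1` budget; when `k2 > 0`
#' a sparse error vector absorbs the `k2` largest-magnitude residual entries
#' (gross observation errors such as a mis-placed landmark) and the code is
#' refit on the remaining rows. `method = "ista"` instead solves the l1
#' relaxation with weights `lambda1` (code) and `lambda2` (error).
#'
#' @param y numeric observation (length = rows of `D`).
#' @param D dictionary matrix (p x k), columns are atoms.
#' @param k1 sparsity budget for the code `x`.
#' @param k2 sparsity budget for the error `e` (default 0).
#' @param lambda1,lambda2 l1 weights for the `"ista"` method.
#' @param method `"omp"` (default) or `"ista"`.
#' @return object of class `sparse_fit`: `x`, `e`, `residual` (l2 of
#'   `y - Dx - e`), `support`.
#' @export
sparse_code <- function(y, D, k1, k2 = 0L, lambda1 = 0.1, lambda2 = 10,
                        method = c("omp", "ista")) {
  method <- match.arg(method)
  y <- as.numeric(y); D <- as.matrix(D)
  if (length(y) != nrow(D)) stopf("observation length %d != dictionary rows %d",
                                  length(y), nrow(D))
  if (all(D == 0)) stopf("zero dictionary")
  e <- numeric(length(y))
  if (method == "omp") {
    fit <- omp_pursuit(D, y, k1)
    x <- fit$X[, 1]
    if (k2 > 0L) {
      # alternate: locate the k2 largest residual entries, refit the code on
      # the remaining rows, until the error support stabilizes
      idx <- integer(0)
      for (pass in 1:10) {
        r <- y - D %*% x
        new_idx <- order(abs(r), decreasing = TRUE)[seq_len(min(k2, length(y)))]
        if (setequal(new_idx, idx)) break
        idx <- new_idx
        rows <- setdiff(seq_along(y), idx)
        x <- omp_pursuit(D[rows, , drop = FALSE], y[rows], k1)$X[, 1]
      }
      e[idx] <- (y - D %*% x)[idx]
    }
  } else {
    x <- ista_solve(D, y, lambda1)
    if (k2 > 0L) {
      r <- as.numeric(y - D %*% x)
      e <- sign(r) * pmax(abs(r) - lambda2, 0)
      ord <- order(abs(e), decreasing = TRUE)
      if (length(ord) > k2) e[ord[-seq_len(k2)]] <- 0
      x <- ista_solve(D, y - e, lambda1)
    }
  }
  res <- sqrt(sum((y - D %*% x - e)^2))
  structure(list(x = as.numeric(x), e = e, residual = res,
                 support = which(x != 0), beta = NULL),
            class = "sparse_fit")
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("<sparse_fit> %d/%d nonzero coefficients, residual %.4g%s\n",
              length(x$support), length(x$x), x$residual,
              if (is.null(x$beta)) "" else "; with transfer"))
  invisible(x)
}

#' Fit sparse code and transfer from landmark observations
#'
#' Alternates (a) estimating the similarity transfer that carries the observed
#' landmark points into the aligned model frame (pairwise Procrustes on the
#' landmark point sets) and (b) sparse-coding the transferred observation
#' against the landmark dictionary, until the residual stabilizes.
#'
#' @param y_L l x 3 matrix of observed landmark world points (mm), rows in
#'   dictionary landmark order; or a world-mode [landmark_set()].
#' @param dict a [build_dictionaries()] result.
#' @param k1 code sparsity (default `ceiling(k / 2)`).
#' @param k2 error sparsity in entries (3 per landmark), default 0.
#' @param lambda1,lambda2,method passed to [sparse_code()].
#' @param tol relative residual-change stop, default 1e-10.
#' @param max_iter alternation cap.
#' @return `sparse_fit` with the transfer in `$beta`
#'   (a [similarity_transform()] mapping image world -> model frame) and the
#'   objective trace in `$trace`.
#' @export
fit_transfer <- function(y_L, dict, k1 = NULL, k2 = 0L, lambda1 = 0.1,
                         lambda2 = 10, method = "omp", tol = 1e-10,
                         max_iter = 50L) {
  if (inherits(y_L, "landmark_set")) y_L <- landmark_points(y_L)
  y_L <- as.matrix(y_L)
  l <- nrow(y_L)
  if (l < 3L) stopf("at least 3 landmarks are needed to determine the transfer")
  if (3L * l != nrow(dict$D_L))
    stopf("landmark count %d does not match dictionary (%d)", l,
          nrow(dict$D_L) / 3L)
  k1 <- k1 %||% ceiling(dict$k / 2)
  model_lm <- matrix(rowMeans(dict$D_L), ncol = 3, byrow = TRUE)
  fit <- NULL; beta <- NULL
  prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    al <- align_pair(model_lm, y_L)
    beta <- al$transform
    yt <- as.numeric(t(al$aligned))
    fit <- sparse_code(yt, dict$D_L, k1 = k1, k2 = k2, lambda1 = lambda1,
                       lambda2 = lambda2, method = method)
    trace <- c(trace, fit$residual)
    model_lm <- matrix(dict$D_L %*% fit$x, ncol = 3, byrow = TRUE)
    if (abs(prev - fit$residual) < tol * (1 + prev)) break
    prev <- fit$residual
  }
  fit$beta <- beta
  fit$trace <- trace
  fit
}

#' Instantiate the sparse statistical shape model in image coordinates
#'
#' Reconstructs `Y_S = D_S x` in the aligned model frame and carries it back
#' to image world coordinates through the inverse of the fitted transfer.
#'
#' @param dict a [build_dictionaries()] result.
#' @param fit a [sparse_code()]/[fit_transfer()] result (`$beta` may be NULL
#'   for identity transfer).
#' @return a [corr_shape()] with the family topology.
#' @export
instantiate_model <- function(dict, fit) {
  ys <- matrix(dict$D_S %*% fit$x, ncol = 3, byrow = TRUE)
  if (!is.null(fit$beta)) ys <- apply_transform(invert_transform(fit$beta), ys)
  corr_shape(ys, dict$faces, dict$family_id)
}

#' K-SVD dictionary learning
#'
#' Alternates batch orthogonal pursuit with rank-1 (SVD) atom updates. Atoms
#' are unit norm. An atom used by no sample is re-seeded from the currently
#' worst-represented training column. Deterministic given `seed`.
#'
#' @param Y p x N training matrix (columns are samples).
#' @param n_atoms number of atoms (`<= N`).
#' @param k1 pursuit sparsity.
#' @param n_iter alternation count; 0 returns the initialization.
#' @param seed integer seed for the initial atom draw.
#' @return list: `D` (p x n_atoms, unit columns), `X` (codes), `errors`
#'   (per-iteration mean squared reconstruction error, non-increasing).
#' @export
ksvd <- function(Y, n_atoms, k1, n_iter = 10L, seed = 1L) {
  Y <- as.matrix(Y)
  if (n_atoms > ncol(Y)) stopf("n_atoms (%d) exceeds training columns (%d)",
                               n_atoms, ncol(Y))
  D <- local_seed(seed, {
    init <- sample.int(ncol(Y), n_atoms)
    Y[, init, drop = FALSE]
  })
  nz <- sqrt(colSums(D^2))
  nz[nz == 0] <- 1
  D <- sweep(D, 2, nz, "/")
  X <- NULL
  errors <- numeric(0)
  if (n_iter == 0L) {
    fit <- omp_pursuit(D, Y, k1)
    return(list(D = D, X = fit$X, errors = mean(fit$residual^2)))
  }
  for (it in seq_len(n_iter)) {
    fit <- omp_pursuit(D, Y, k1)
    X <- fit$X
    for (a in seq_len(n_atoms)) {
      users <- which(X[a, ] != 0)
      if (!length(users)) {
        # re-seed dead atom from the worst-represented sample
        worst <- which.max(fit$residual)
        v <- Y[, worst]
        nv <- sqrt(sum(v^2)); if (nv == 0) nv <- 1
        D[, a] <- v / nv
        next
      }
      E <- Y[, users, drop = FALSE] -
        D[, -a, drop = FALSE] %*% X[-a, users, drop = FALSE]
      sv <- svd(E, nu = 1, nv = 1)
      D[, a] <- sv$u[, 1]
      X[a, users] <- sv$d[1] * sv$v[, 1]
    }
    fit <- omp_pursuit(D, Y, k1)
    X <- fit$X
    errors <- c(errors, mean(fit$residual^2))
  }
  list(D = D, X = X, errors = errors)
}
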