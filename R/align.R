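# Generalized Procrustes alignment of a correspondence family.
#
# The classic planar formulation (squared vertex distances, barycentre, shape
# size) is carried over to 3-D by summing the z term the same way; rotations
# are the full 3-D Euler product.

#' Similarity transform v -> s * R v + t
#' @param scale positive scalar.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 mm.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (scale <= 0) stopf("scale must be positive")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      det(rotation) < 0)
    stopf("rotation must be orthonormal with determinant +1")
  structure(list(scale = as.numeric(scale), rotation = rotation,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points or a shape
#' @param tf a [similarity_transform()].
#' @param x n x 3 matrix or [corr_shape()].
#' @export
apply_transform <- function(tf, x) {
  if (inherits(x, "corr_shape")) {
    x$vertices <- apply_transform(tf, x$vertices)
    return(x)
  }
  sweep(tf$scale * (rbind(x) %*% t(tf$rotation)), 2, tf$translation, "+")
}

#' Inverse of a similarity transform
#' @param tf a [similarity_transform()].
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  similarity_transform(1 / tf$scale, Rt,
                       -(Rt %*% tf$translation) / tf$scale)
}

#' Squared Procrustes distance between two corresponding shapes (mm^2)
#'
#' `Pd^2 = sum_j ||v_j1 - v_j2||^2` over corresponding vertices.
#' @param s1,s2 [corr_shape()]s (or n x 3 matrices) with equal vertex count.
#' @export
procrustes_distance <- function(s1, s2) {
  v1 <- if (inherits(s1, "corr_shape")) s1$vertices else as.matrix(s1)
  v2 <- if (inherits(s2, "corr_shape")) s2$vertices else as.matrix(s2)
  if (nrow(v1) != nrow(v2)) stopf("vertex counts differ (%d vs %d)", nrow(v1), nrow(v2))
  sum((v1 - v2)^2)
}

#' Barycentre of a shape (mm)
#' @param s a [corr_shape()] or n x 3 matrix.
#' @export
centroid <- function(s) {
  v <- if (inherits(s, "corr_shape")) s$vertices else rbind(s)
  colMeans(v)
}

#' Centroid size of a shape (mm)
#'
#' Frobenius norm of the centred vertex matrix,
#' `R(n) = sqrt(sum_j ||v_j - centroid||^2)`.
#' @param s a [corr_shape()] or n x 3 matrix.
#' @export
shape_size <- function(s) {
  v <- if (inherits(s, "corr_shape")) s$vertices else rbind(s)
  sqrt(sum(sweep(v, 2, colMeans(v))^2))
}

#' Euler rotation matrix R_x(phi) R_y(psi) R_z(phi2)
#'
#' The product of the three printed axis rotations, in that order; note the
#' y-axis factor uses the -sin(psi) in its (1,3) entry.
#' @param phi,psi,phi2 angles in radians about x, y, z.
#' @export
rotation_matrix <- function(phi, psi, phi2) {
  rx <- rbind(c(1, 0, 0),
              c(0, cos(phi), -sin(phi)),
              c(0, sin(phi), cos(phi)))
  ry <- rbind(c(cos(psi), 0, -sin(psi)),
              c(0, 1, 0),
              c(sin(psi), 0, cos(psi)))
  rz <- rbind(c(cos(phi2), -sin(phi2), 0),
              c(sin(phi2), cos(phi2), 0),
              c(0, 0, 1))
  rx %*% ry %*% rz
}

# Kabsch rotation mapping centred B onto centred A (det +1 enforced by
# flipping the smallest-singular-value column).
kabsch <- function(a_centred, b_centred) {
  m <- crossprod(a_centred, b_centred) # 3x3 = A^T B
  sv <- svd(m)
  d <- det(sv$u %*% t(sv$v))
  s <- diag(c(1, 1, sign(d)))
  sv$u %*% s %*% t(sv$v)
}

#' Similarity-align one shape onto another (pairwise Procrustes)
#'
#' Steps: centre both, rescale the moving shape to the fixed shape's size,
#' align barycentres, then rotate by the SVD of the 3 x 3 cross-covariance
#' (reflections corrected to det +1).
#'
#' @param s1 fixed [corr_shape()] (or matrix).
#' @param s2 moving shape with the same vertex count.
#' @return list with `aligned` (s2 mapped into s1's frame) and `transform`
#'   (the [similarity_transform()] that maps original s2 coordinates there).
#' @export
align_pair <- function(s1, s2) {
  v1 <- if (inherits(s1, "corr_shape")) s1$vertices else as.matrix(rbind(s1))
  v2 <- if (inherits(s2, "corr_shape")) s2$vertices else as.matrix(rbind(s2))
  if (nrow(v1) != nrow(v2)) stopf("vertex counts differ (%d vs %d)", nrow(v1), nrow(v2))
  c1 <- colMeans(v1); c2 <- colMeans(v2)
  a <- sweep(v1, 2, c1); b <- sweep(v2, 2, c2)
  r1 <- sqrt(sum(a^2)); r2 <- sqrt(sum(b^2))
  if (r2 == 0 || sum(svd(b)$d > max(dim(b)) * 1e-12 * max(svd(b)$d, 1)) < 2)
    stopf("degenerate (rank < 2) point set cannot be aligned")
  s <- if (r1 > 0) r1 / r2 else 1
  rot <- kabsch(a, b * s)
  tf <- similarity_transform(s, rot, c1 - s * (rot %*% c2))
  aligned <- if (inherits(s2, "corr_shape")) apply_transform(tf, s2)
             else apply_transform(tf, v2)
  list(aligned = aligned, transform = tf)
}

#' Generalized Procrustes analysis of a shape family
#'
#' Iterates: translate to the origin, similarity-align every shape to the
#' current mean, recompute the mean `S_bar = (1/k) sum S_i`, and rescale the
#' mean to unit centroid size (the classic guard against scale drift), until
#' the mean-shape change falls below `eps`.
#'
#' @param shapes list of [corr_shape()]s with a common vertex count.
#' @param eps convergence threshold on the root squared mean-shape change
#'   (units of the unit-size mean); default 1e-6.
#' @param max_iter iteration cap; non-convergence sets a flag, not an error.
#' @return list: `aligned` (list of shapes in the common frame), `mean`
#'   ([corr_shape()], unit centroid size), `iterations`, `converged`,
#'   `residuals` (per-shape Pd^2 to the mean).
#' @export
gpa <- function(shapes, eps = 1e-6, max_iter = 100L) {
  if (length(shapes) < 2L) stopf("gpa needs at least two shapes")
  n <- vapply(shapes, function(s) nrow(s$vertices), 1L)
  if (length(unique(n)) != 1L) stopf("all shapes must share a vertex count")
  vs <- lapply(shapes, function(s) sweep(s$vertices, 2, colMeans(s$vertices)))
  mean_v <- vs[[1]] / shape_size(vs[[1]])
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    vs <- lapply(vs, function(v) align_pair(mean_v, v)$aligned)
    new_mean <- Reduce(`+`, vs) / length(vs)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    sz <- shape_size(new_mean)
    if (sz == 0) stopf("degenerate mean shape in gpa")
    new_mean <- new_mean / sz
    delta <- sqrt(procrustes_distance(new_mean, mean_v))
    mean_v <- new_mean
    if (delta < eps) { converged <- TRUE; break }
  }
  if (!converged) warnf("gpa did not converge in %d iterations", max_iter)
  aligned <- mapply(function(s, v) { s$vertices <- v; s }, shapes, vs,
                    SIMPLIFY = FALSE)
  mean_shape <- corr_shape(mean_v, shapes[[1]]$faces, shapes[[1]]$family_id)
  list(aligned = aligned, mean = mean_shape, iterations = it,
       converged = converged,
       residuals = vapply(vs, function(v) procrustes_distance(v, mean_v), 1.0))
}
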