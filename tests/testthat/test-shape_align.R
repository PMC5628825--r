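# Procrustes machinery: distances, sizes, rotations, pairwise and
# generalized alignment, and correspondence-preserving downsampling.

test_that("procrustes_distance matches the per-vertex sum oracle", {
  s1 <- matrix(rnorm(12), 4, 3)
  expect_equal(procrustes_distance(s1, s1), 0)
  s2 <- s1; s2[, 1] <- s2[, 1] + 1
  expect_equal(procrustes_distance(s1, s2), 4.0) # 4 vertices, 1 mm^2 each
  set.seed(11)
  for (i in 1:20) {
    a <- matrix(rnorm(30), 10, 3); b <- matrix(rnorm(30), 10, 3)
    oracle <- 0
    for (j in 1:10) oracle <- oracle + sum((a[j, ] - b[j, ])^2)
    expect_equal(procrustes_distance(a, b), oracle, tolerance = 1e-12)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  }
  expect_error(procrustes_distance(matrix(0, 3, 3), matrix(0, 4, 3)), "differ")
})

test_that("centroid and shape size follow their closed forms", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(centroid(sq), c(0.5, 0.5, 0))
  expect_equal(centroid(rbind(c(3, -2, 7))), c(3, -2, 7))
  expect_equal(shape_size(sq), sqrt(2))
  expect_equal(shape_size(matrix(5, 6, 3)), 0)
  set.seed(4)
  cl <- matrix(rnorm(60), 20, 3)
  expect_equal(centroid(cl), colMeans(cl))
  expect_equal(shape_size(2 * cl), 2 * shape_size(cl))
})

test_that("the Euler rotation matrix matches its printed factor product", {
  expect_equal(rotation_matrix(0, 0, 0), diag(3))
  # quarter turn about x maps +y to +z under the printed sign convention
  expect_equal(as.numeric(rotation_matrix(pi / 2, 0, 0) %*% c(0, 1, 0)),
               c(0, 0, 1), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:100) {
    ang <- runif(3, -pi, pi)
    r <- rotation_matrix(ang[1], ang[2], ang[3])
    expect_lt(max(abs(crossprod(r) - diag(3))), 1e-12)
    expect_equal(det(r), 1, tolerance = 1e-12)
    # independent evaluation of the three printed factors
    rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                   0, -sin(ang[1]), cos(ang[1])), 3, 3)
    ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                   -sin(ang[2]), 0, cos(ang[2])), 3, 3)
    rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]),
                   0, 0, 0, 1), 3, 3)
    expect_equal(r, rx %*% ry %*% rz, tolerance = 1e-14)
  }
})

test_that("align_pair recovers known similarity transforms exactly", {
  set.seed(21)
  s1 <- matrix(rnorm(45), 15, 3)
  r <- rotation_matrix(0.4, -1.1, 2.0)
  s2 <- t(1.37 * r %*% t(s1)) + matrix(c(4, -3, 9), 15, 3, byrow = TRUE)
  res <- align_pair(s2, s1) # map s1 onto s2
  expect_lt(procrustes_distance(res$aligned, s2), 1e-8)
  expect_equal(res$transform$scale, 1.37, tolerance = 1e-9)
  back <- align_pair(s1, s2)
  expect_equal(back$transform$scale, 1 / 1.37, tolerance = 1e-9)
})

test_that("reflected shapes align with a proper rotation and nonzero residual", {
  set.seed(22)
  s1 <- matrix(rnorm(60), 20, 3)
  s2 <- s1 %*% diag(c(-1, 1, 1)) # reflection
  res <- align_pair(s1, s2)
  expect_equal(det(res$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(procrustes_distance(res$aligned, s1), 1e-4)
  # Monte-Carlo lower bound: no random proper similarity beats the SVD fit
  best <- procrustes_distance(res$aligned, s1)
  c1 <- colMeans(s1); c2 <- colMeans(s2)
  r1 <- shape_size(s1); r2 <- shape_size(s2)
  for (i in 1:1000) {
    rr <- rotation_matrix(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    cand <- sweep((r1 / r2) * sweep(s2, 2, c2) %*% t(rr), 2, c1, "+")
    expect_gte(procrustes_distance(cand, s1) + 1e-9, best)
  }
})

test_that("align_pair rejects degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), -(1:5)) # rank 1
  expect_error(align_pair(matrix(rnorm(15), 5, 3), line), "degenerate")
})

test_that("gpa aligns transformed copies of one shape in few iterations", {
  base <- sphere_shape(2, radius = 10)
  set.seed(31)
  fam <- lapply(1:8, function(i) {
    r <- rotation_matrix(runif(1, -pi, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    s <- base
    s$vertices <- t(exp(runif(1, -0.3, 0.3)) * r %*% t(base$vertices)) +
      matrix(runif(3, -20, 20), nrow(base$vertices), 3, byrow = TRUE)
    s
  })
  g <- gpa(fam)
  expect_true(g$converged)
  expect_lte(g$iterations, 3L)
  expect_lt(max(g$residuals), 1e-6)
  expect_equal(shape_size(g$mean), 1, tolerance = 1e-9)
})

test_that("the gpa mean of two shapes is their aligned midpoint", {
  set.seed(32)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, 0, 0.1), 10, 3)
  g <- gpa(list(corr_shape(a), corr_shape(b)))
  mid <- (g$aligned[[1]]$vertices + g$aligned[[2]]$vertices) / 2
  mid <- sweep(mid, 2, colMeans(mid))
  mid <- mid / shape_size(mid)
  expect_lt(procrustes_distance(g$mean, mid), 1e-10)
})

test_that("gpa output is invariant to similarity transforms of the inputs", {
  set.seed(33)
  fam <- lapply(1:4, function(i) corr_shape(matrix(rnorm(45), 15, 3) * 5))
  g1 <- gpa(fam)
  fam2 <- fam
  r <- rotation_matrix(1.0, -0.5, 0.3)
  fam2[[2]]$vertices <- t(2.5 * r %*% t(fam2[[2]]$vertices)) +
    matrix(c(7, 7, -7), 15, 3, byrow = TRUE)
  g2 <- gpa(fam2)
  for (i in 1:4)
    expect_lt(max(abs(g1$aligned[[i]]$vertices - g2$aligned[[i]]$vertices)), 1e-6)
})

row_norms_test <- function(m) sqrt(rowSums(m * m))

test_that("downsampling preserves correspondence across the family", {
  sph <- sphere_shape(2, radius = 10) # 162 vertices
  out <- downsample_with_correspondence(list(sph, sph, sph), 42L)
  expect_true(all(vapply(out, function(s) nrow(s$vertices), 1L) == 42L))
  expect_equal(procrustes_distance(out[[1]], out[[2]]), 0, tolerance = 1e-18)
  expect_equal(procrustes_distance(out[[1]], out[[3]]), 0, tolerance = 1e-18)

  # scaled copy: corresponding vertices sit on the same radial directions
  big <- sph; big$vertices <- sph$vertices * 1.1
  out2 <- downsample_with_correspondence(list(sph, big), 42L)
  d1 <- out2[[1]]$vertices / row_norms_test(out2[[1]]$vertices)
  d2 <- out2[[2]]$vertices / row_norms_test(out2[[2]]$vertices)
  ang <- acos(pmin(1, rowSums(d1 * d2)))
  expect_lt(max(ang), 1e-3)
  # and the mapped copy lies at the scaled radius
  expect_equal(mean(row_norms_test(out2[[2]]$vertices)) /
                 mean(row_norms_test(out2[[1]]$vertices)), 1.1, tolerance = 0.01)

  expect_error(downsample_with_correspondence(list(sph), 200L), "exceeds")
  open_mesh <- corr_shape(sph$vertices, sph$faces[-1, ])
  expect_error(downsample_with_correspondence(list(open_mesh), 42L), "closed")
})
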