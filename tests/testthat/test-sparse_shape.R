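# Shape dictionaries, orthogonal pursuit, landmark transfer fitting,
# model instantiation and K-SVD.

test_that("dictionaries stack flattened shapes with landmark row restriction", {
  set.seed(41)
  one <- corr_shape(matrix(rnorm(30), 10, 3))
  d1 <- build_dictionaries(list(one), c(2L, 5L))
  expect_equal(ncol(d1$D_S), 1L)
  expect_equal(d1$D_S[, 1], as.numeric(t(one$vertices)))
  expect_equal(d1$D_L[, 1], as.numeric(t(one$vertices[c(2, 5), ])))

  shapes <- lapply(1:6, function(i) corr_shape(matrix(rnorm(1500), 500, 3)))
  d <- build_dictionaries(shapes, 1:500)
  expect_equal(dim(d$D_S), c(1500L, 6L))
  expect_identical(d$D_L, d$D_S) # all vertices are landmarks

  bad <- c(shapes[1:2], list(corr_shape(matrix(0, 9, 3))))
  expect_error(build_dictionaries(bad, 1:3), "inconsistent")
})

test_that("pursuit finds single-atom codes and orthogonal residuals", {
  set.seed(42)
  q <- qr.Q(qr(matrix(rnorm(40 * 8), 40, 8)))
  f <- sparse_code(2 * q[, 3], q, k1 = 1)
  expect_equal(f$support, 3L)
  expect_equal(f$x[3], 2, tolerance = 1e-12)
  expect_equal(f$residual, 0, tolerance = 1e-10)

  # an observation orthogonal to the span keeps its full norm as residual
  y_perp <- matrix(rnorm(40), 40, 1)
  y_perp <- y_perp - q %*% crossprod(q, y_perp)
  f2 <- sparse_code(y_perp, q, k1 = 3)
  expect_equal(f2$residual, sqrt(sum(y_perp^2)), tolerance = 1e-8)
  expect_error(sparse_code(rnorm(40), matrix(0, 40, 4), 1), "zero dictionary")
})

test_that("2-sparse support recovery matches the exhaustive-support oracle", {
  set.seed(43)
  hits <- 0L
  for (trial in 1:30) {
    d <- matrix(rnorm(40 * 8), 40, 8)
    xt <- numeric(8)
    sup <- sample(8, 2)
    xt[sup] <- runif(2, 0.5, 2) * sample(c(-1, 1), 2, replace = TRUE)
    y <- d %*% xt
    f <- sparse_code(y, d, k1 = 2)
    # oracle: least squares over all C(8,2) supports
    combos <- utils::combn(8, 2)
    errs <- apply(combos, 2, function(s) {
      sum(stats::lm.fit(d[, s], y)$residuals^2)
    })
    oracle_sup <- sort(combos[, which.min(errs)])
    expect_equal(sort(f$support), oracle_sup)
    if (identical(sort(f$support), sort(sup))) hits <- hits + 1L
  }
  expect_equal(hits, 30L)
})

test_that("pursuit residual is non-increasing in the sparsity budget", {
  set.seed(44)
  for (trial in 1:10) {
    d <- matrix(rnorm(30 * 10), 30, 10)
    y <- rnorm(30)
    res <- vapply(1:8, function(k1) sparse_code(y, d, k1)$residual, 1.0)
    expect_true(all(diff(res) <= 1e-9))
  }
})

test_that("the sparse error term absorbs gross observation errors", {
  set.seed(45)
  d <- matrix(rnorm(30 * 6), 30, 6)
  xt <- numeric(6); xt[c(1, 4)] <- c(1.2, -0.8)
  y <- as.numeric(d %*% xt)
  bad_rows <- c(7, 8, 9)
  y[bad_rows] <- y[bad_rows] + c(25, -30, 20)
  f <- sparse_code(y, d, k1 = 2, k2 = 3)
  expect_setequal(which(f$e != 0), bad_rows)
  # leave-out refit oracle: code fitted on the clean rows only
  clean <- setdiff(seq_len(30), bad_rows)
  f_clean <- sparse_code(y[clean], d[clean, ], k1 = 2)
  expect_equal(sort(f$support), sort(f_clean$support))
  expect_equal(f$x, f_clean$x, tolerance = 1e-8)
})

test_that("full-sparsity pursuit equals least-squares reconstruction", {
  set.seed(46)
  shapes <- lapply(1:5, function(i) corr_shape(matrix(rnorm(60), 20, 3)))
  d <- build_dictionaries(shapes, c(1L, 7L, 13L, 20L))
  y <- rnorm(60)
  f <- sparse_code(y, d$D_S, k1 = 5)
  ls <- qr.solve(d$D_S, y)
  expect_equal(f$x, as.numeric(ls), tolerance = 1e-6)
})

test_that("fit_transfer recovers a known transform and prior indicator", {
  set.seed(47)
  shapes <- lapply(1:6, function(i)
    corr_shape(sphere_shape(1)$vertices + matrix(rnorm(126, 0, 0.1), 42, 3)))
  lm_idx <- c(1L, 5L, 9L, 20L, 30L, 37L, 42L)
  dict <- build_dictionaries(shapes, lm_idx)
  r <- rotation_matrix(0.2, 0.5, -0.4)
  tf <- similarity_transform(30, r, c(100, 90, 80))
  y_l <- apply_transform(tf, shapes[[4]]$vertices[lm_idx, ])
  fit <- fit_transfer(y_l, dict, k1 = 1)
  expect_equal(fit$support, 4L)
  expect_lt(fit$residual, 1e-6)
  # the code coefficient and the transfer scale are only jointly identified:
  # beta maps the observation onto the coefficient-scaled atom
  expect_lt(max(abs(apply_transform(fit$beta, y_l) -
                      fit$x[4] * shapes[[4]]$vertices[lm_idx, ])), 1e-6)
  # and the instantiated model reproduces prior 4 in image coordinates
  inst <- instantiate_model(dict, fit)
  expect_lt(max(abs(inst$vertices - apply_transform(tf, shapes[[4]]$vertices))),
            1e-5)
  # its landmark rows agree with the observed landmarks within the residual
  expect_lt(max(abs(inst$vertices[lm_idx, ] - y_l)), 1e-5)
  # objective trace is non-increasing
  expect_true(all(diff(fit$trace) <= 1e-9))
})

test_that("the mean observation takes near-uniform weights at full sparsity", {
  set.seed(48)
  shapes <- lapply(1:5, function(i) corr_shape(matrix(rnorm(90), 30, 3) + 50))
  lm_idx <- 1:30
  dict <- build_dictionaries(shapes, lm_idx)
  y_l <- matrix(rowMeans(dict$D_L), ncol = 3, byrow = TRUE)
  fit <- fit_transfer(y_l, dict, k1 = 5)
  ls <- qr.solve(dict$D_L, as.numeric(t(apply_transform(fit$beta, y_l))))
  expect_equal(fit$x, as.numeric(ls), tolerance = 1e-6)
  expect_equal(fit$x, rep(0.2, 5), tolerance = 1e-6)
})

test_that("instantiate_model honours identity and translation transfers", {
  set.seed(49)
  shapes <- lapply(1:4, function(i) corr_shape(matrix(rnorm(36), 12, 3)))
  dict <- build_dictionaries(shapes, c(2L, 6L, 11L))
  ind <- structure(list(x = c(0, 0, 1, 0), e = numeric(9), beta = NULL,
                        residual = 0), class = "sparse_fit")
  expect_equal(instantiate_model(dict, ind)$vertices, shapes[[3]]$vertices)
  ind$beta <- similarity_transform(1, diag(3), c(-5, 2, 8))
  shifted <- instantiate_model(dict, ind)$vertices
  expect_equal(shifted, shapes[[3]]$vertices - # inverse of the transfer
                 matrix(c(-5, 2, 8), 12, 3, byrow = TRUE))
})

test_that("fit_transfer refuses under-determined landmark sets", {
  shapes <- lapply(1:3, function(i) corr_shape(matrix(rnorm(30), 10, 3)))
  dict <- build_dictionaries(shapes, c(1L, 2L))
  expect_error(fit_transfer(matrix(0, 2, 3), dict), "at least 3")
})

test_that("ksvd recovers orthogonal generating atoms and is monotone", {
  set.seed(50)
  a <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
  y <- a[, sample(1:3, 80, replace = TRUE)] * rep(runif(80, 0.5, 2), each = 20)
  kd <- ksvd(y, n_atoms = 3, k1 = 1, n_iter = 10, seed = 6)
  dots <- apply(abs(crossprod(kd$D, a)), 2, max)
  expect_true(all(dots > 0.99))
  expect_true(all(diff(kd$errors) <= 1e-9))
  expect_lt(max(abs(sqrt(colSums(kd$D^2)) - 1)), 1e-9)

  # n_iter = 0 returns the (seeded, normalized) initialization
  kd0 <- ksvd(y, n_atoms = 3, k1 = 1, n_iter = 0, seed = 6)
  init <- local({
    set.seed(6); cols <- sample.int(80, 3)
    m <- y[, cols]; sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
  expect_equal(kd0$D, init, ignore_attr = TRUE)
  expect_error(ksvd(y, n_atoms = 100, k1 = 1), "exceeds")
})

test_that("the l1 relaxation route approximates and shrinks as expected", {
  set.seed(51)
  d <- qr.Q(qr(matrix(rnorm(40 * 6), 40, 6))) * 3
  xt <- numeric(6); xt[c(2, 5)] <- c(2, -1.5)
  y <- as.numeric(d %*% xt)
  # small l1 weight: close to the exact code
  f <- sparse_code(y, d, k1 = 2, lambda1 = 1e-4, method = "ista")
  expect_lt(max(abs(f$x - xt)), 1e-2)
  # overwhelming l1 weight drives the code to zero
  f0 <- sparse_code(y, d, k1 = 2, lambda1 = 1e6, method = "ista")
  expect_true(all(f0$x == 0))
  expect_equal(f0$residual, sqrt(sum(y^2)), tolerance = 1e-9)
})
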