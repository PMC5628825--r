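# Profile sampling, the weighted Gaussian mixture, and the region /
# statistical / specific boundary energies.

test_that("profile samples sit at the prescribed offsets", {
  vol <- ramp_volume(c(30, 20, 20))
  p <- sample_profile(vol, c(14, 10, 10), c(1, 0, 0), m = 11, L = 10)
  expect_equal(p$values[6], 14, tolerance = 1e-10) # middle sample on the vertex
  expect_equal(p$step, 1)
  # linear ramp: sample i reads the x-coordinate of its analytic position
  off <- ((1:11 - 1) / 10 - 0.5) * 10
  expect_equal(p$values, 14 + off, tolerance = 1e-6)

  const <- scalar_volume(array(7, c(10, 10, 10)))
  pc <- sample_profile(const, c(5, 5, 5), c(0, 0, 1), m = 7, L = 3)
  expect_true(all(pc$values == 7))
  expect_error(sample_profile(vol, c(500, 10, 10), c(1, 0, 0), 11, 10),
               "outside")
  expect_error(sample_profile(vol, c(14, 10, 10), c(2, 0, 0), 11, 10), "unit")
})

test_that("batch profile sampling equals the per-vertex path", {
  set.seed(61)
  vol <- scalar_volume(array(rnorm(8000), c(20, 20, 20)))
  verts <- matrix(runif(30, 6, 13), 10, 3)
  nrm <- matrix(rnorm(30), 10, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  batch <- spssm:::sample_profiles(vol, verts, nrm, 9, 8)
  for (j in 1:10) {
    single <- sample_profile(vol, verts[j, ], nrm[j, ], 9, 8)
    expect_equal(batch$values[, j], single$values, tolerance = 1e-12)
  }
})

test_that("the five-component mixture recovers its generator", {
  set.seed(62)
  mus <- c(30, 80, 120, 180, 240); sds <- c(8, 6, 12, 10, 14)
  ws <- c(0.15, 0.3, 0.2, 0.2, 0.15)
  comp <- sample(1:5, 20000, replace = TRUE, prob = ws)
  x <- rnorm(20000, mus[comp], sds[comp])
  fit <- fit_wgmm(x, 5)
  expect_true(all(abs(fit$means - mus) < 2))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # peak-height selection: component 2 has the largest w / sigma here
  expect_equal(fit$organ_component, 2L)
  expect_equal(fit$heights, fit$weights / fit$sds)
  expect_equal(fit$G_L, fit$means[2] - 1.5 * fit$sds[2])
  expect_equal(fit$G_U, fit$means[2] + 1.5 * fit$sds[2])
})

test_that("a dominant narrow component is selected with the printed band", {
  set.seed(63)
  x <- c(rnorm(6000, 100, 10), runif(4000, 0, 300))
  fit <- fit_wgmm(x, 5)
  m <- fit$organ_component
  expect_equal(fit$G_m, fit$means[m])
  expect_lt(abs(fit$G_m - 100), 5)
  # mu_m = 100, sigma_m = 10 must give exactly (85, 115)
  expect_equal(100 - 1.5 * 10, 85)
  expect_equal(100 + 1.5 * 10, 115)
  expect_equal(fit$G_L, fit$means[m] - 1.5 * fit$sds[m], tolerance = 1e-12)
  expect_error(fit_wgmm(c(1, 2, 3), 5), "distinct")
})

test_that("region energy walks outward exactly as the procedure states", {
  # all samples in band: the walk traverses from the centre to the outer end
  expect_equal(region_energy(rep(100, 11), 0.5, 90, 110), 5 * 0.5)
  # out-of-band centre sample gives zero
  expect_equal(region_energy(c(rep(100, 5), 200, rep(100, 5)), 1, 90, 110), 0)
  # in-band up to t samples beyond the centre: displacement t * step
  p <- c(rep(100, 5), 100, 100, 100, 200, 200, 200)
  expect_equal(region_energy(p, 1, 90, 110), 2)
  # batch path equals the scalar walk on random profiles
  set.seed(64)
  pm <- matrix(runif(11 * 50, 80, 120), 11, 50)
  inb <- pm >= 90 & pm <= 110
  batch <- spssm:::region_energy_batch(inb, 1, 6L)
  scalar <- vapply(1:50, function(j) region_energy(pm[, j], 1, 90, 110), 1.0)
  expect_equal(batch, scalar)
})

test_that("profile statistics match hand evaluation over training pairs", {
  sph <- sphere_shape(1, radius = 6, centre = c(10, 10, 10))
  const1 <- scalar_volume(array(50, c(21, 21, 21)))
  expect_error(train_profile_stats(list(sph), list(const1)), "at least 2")
  st <- train_profile_stats(list(sph, sph), list(const1, const1))
  expect_equal(dim(st$mu), c(11L, 42L))
  expect_true(all(st$mu == 50))
  expect_true(all(st$sigma == 1e-3)) # degenerate variance floored

  # two constant volumes offset by delta: sd = delta / sqrt(2) * sqrt(2) form
  const2 <- scalar_volume(array(58, c(21, 21, 21)))
  st2 <- train_profile_stats(list(sph, sph), list(const1, const2))
  expect_equal(st2$mu[1, 1], 54)
  expect_equal(st2$sigma[1, 1], stats::sd(c(50, 58)), tolerance = 1e-12)
})

test_that("statistical energy peaks at the trained boundary position", {
  set.seed(65)
  mu <- c(10, 10, 10, 10, 10, 55, 100, 100, 100, 100, 100) # step template
  sg <- rep(2, 11)
  profile <- c(rep(10, 5), mu, rep(100, 5)) # template centred in a 21-sample profile
  e <- statistics_energy(profile, mu, sg, 5, 5)
  expect_equal(length(e), 11L)
  expect_equal(sum(e), 1, tolerance = 1e-12)
  expect_true(all(e >= 0))
  expect_equal(which.max(e), 6L) # centred offset

  # uniform statistics give a uniform (degenerate) energy
  eu <- statistics_energy(rep(3, 21), rep(3, 11), rep(1, 11), 5, 5)
  expect_equal(eu, rep(1 / 11, 11))
})

test_that("specific energy localizes an intensity step", {
  profile <- c(rep(0, 10), rep(100, 11))
  e <- specific_energy(profile, 5, 5, bandwidth = 1e6) # ~uniform kernel
  expect_equal(sum(e), 1, tolerance = 1e-12)
  # the contrast term peaks at the aligned window (6); the spread term of the
  # printed formulas peaks just inside the step, so the combined maximum sits
  # within one window of the boundary
  expect_true(which.max(e) %in% 4:6)
  f1_raw <- vapply(1:11, function(t) {
    w <- profile[t:(t + 10)]
    abs(sum(w[1:5]) / 5 - sum(w[7:11]) / 5)
  }, 1.0)
  # windows 5 and 6 both have an all-0 inner and all-100 outer half
  expect_equal(max(f1_raw), 100)
  expect_true(all(which(f1_raw == 100) %in% 5:6))
  # hand evaluation of the winning window: f1 = |0 - 100| = 100, f2 = 0
  kw <- rep(1, 11)
  w <- profile[6:16]
  f1 <- abs(sum(w[1:5]) / 5 - sum(w[7:11]) / 5)
  expect_equal(f1, 100)
  expect_equal(stats::var(w[1:5]) - stats::var(w[7:11]), 0)
  # constant profile: degenerate uniform energy
  expect_equal(specific_energy(rep(42, 21), 5, 5), rep(1 / 11, 11))
})

test_that("edge energy combines and tie-breaks as specified", {
  es <- c(0.1, 0.5, 0.2, 0.1, 0.1)
  ep <- c(0.1, 0.1, 0.1, 0.6, 0.1)
  expect_equal(edge_energy(es, ep, alpha = 1)$offset, 2L)
  expect_equal(edge_energy(es, ep, alpha = 0)$offset, 4L)
  comb <- 0.5 * es + 0.5 * ep
  expect_equal(edge_energy(es, ep, alpha = 0.5)$offset, which.max(comb))
  # brute-force scan on random vectors
  set.seed(66)
  for (i in 1:50) {
    a <- runif(9); b <- runif(9)
    got <- edge_energy(a, b, alpha = 0.3, beta_w = 0.7)
    brute <- 0.3 * a + 0.7 * b
    expect_equal(got$score, max(brute))
    expect_equal(got$offset, which.max(brute)) # unique maxima in practice
  }
  # exact tie resolves towards the profile centre
  tie <- c(1, 0, 0, 0, 1)
  expect_equal(edge_energy(tie, tie, alpha = 0.5)$offset, 1L)
  tie2 <- c(0, 1, 0, 1, 0)
  expect_equal(edge_energy(tie2, tie2, alpha = 0.5)$offset, 2L)
  expect_error(edge_energy(es, ep, alpha = 0.7, beta_w = 0.7), "sum to 1")
})

test_that("the vectorized edge energy equals the per-vertex formulas", {
  set.seed(67)
  m_in <- 5L; m_out <- 5L; m <- 11L; M <- 21L
  n <- 25L
  st <- structure(list(mu = matrix(runif(m * n, 40, 60), m, n),
                       sigma = matrix(runif(m * n, 1, 5), m, n),
                       m_in = m_in, m_out = m_out, step = 0.8,
                       bandwidth = m / 4, z = 3L),
                  class = "profile_stats")
  pr <- matrix(runif(M * n, 30, 70), M, n)
  batch <- spssm:::edge_energy_batch(pr, st, alpha = 0.4)
  for (j in seq_len(n)) {
    es <- statistics_energy(pr[, j], st$mu[, j], st$sigma[, j], m_in, m_out,
                            bandwidth = st$bandwidth)
    ep <- specific_energy(pr[, j], m_in, m_out, bandwidth = st$bandwidth)
    ee <- edge_energy(es, ep, alpha = 0.4)
    expect_equal(batch$offset[j], ee$offset)
    expect_equal(batch$score[j], ee$score, tolerance = 1e-12)
    expect_equal(batch$displacement[j], ((ee$offset + m_in) - 11) * st$step)
  }
})
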