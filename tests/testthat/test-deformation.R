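# Mesh voxelization, smoothing, single deformation steps and the full
# segmentation driver on small phantoms.

test_that("voxelization follows the centre-inside rule", {
  cube <- make_cube(10)
  grid <- scalar_volume(array(0, c(12, 12, 12)), c(1, 1, 1), c(-0.5, -0.5, -0.5))
  m <- mesh_to_mask(cube, grid)
  expect_equal(sum(m$data), 1000)
  sph <- sphere_shape(3, radius = 10, centre = c(15, 15, 15))
  gs <- scalar_volume(array(0, c(31, 31, 31)))
  ms <- mesh_to_mask(sph, gs)
  expect_lt(abs(sum(ms$data) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  open_mesh <- corr_shape(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_to_mask(open_mesh, grid), "watertight")
})

test_that("laplacian smoothing is identity at zero and contracts noise", {
  sph <- sphere_shape(2, radius = 10)
  expect_identical(laplacian_smooth(sph, 0)$vertices, sph$vertices)
  set.seed(91)
  noisy <- sph
  noisy$vertices <- noisy$vertices * (1 + rnorm(162, 0, 0.05))
  sm <- laplacian_smooth(noisy, 0.5, 3)
  rv_before <- stats::var(sqrt(rowSums(noisy$vertices^2)))
  rv_after <- stats::var(sqrt(rowSums(sm$vertices^2)))
  expect_lt(rv_after, rv_before)
  # a planar patch is invariant under smoothing of its interior vertex
  plane <- corr_shape(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0.33, 0)),
                      rbind(c(1, 2, 4), c(2, 3, 4), c(3, 1, 4)))
  smp <- laplacian_smooth(plane, 0.7, 2)
  expect_true(all(abs(smp$vertices[, 3]) < 1e-12))
})

test_that("an all-gated state is a fixed point of deform_step", {
  b <- small_phantom_bundle()
  pri <- small_phantom_priors()
  gated_pd <- pri$patch_dict
  gated_pd$sigma_gate <- 1e9 # every patch reconstructs 'well enough'
  wg <- fit_wgmm_volume(b$test$volume, exclude_below = "otsu")
  st <- list(shape = b$test$shape, iteration = 0L)
  out <- deform_step(st, b$test$volume, wg, pri$stats, gated_pd,
                     pri$config)
  expect_true(all(out$gated))
  expect_true(out$converged)
  expect_identical(out$shape$vertices, b$test$shape$vertices)
  expect_true(all(out$displacement == 0))
})

test_that("a shrunken model inflates toward the boundary under the energies", {
  b <- small_phantom_bundle()
  pri <- small_phantom_priors()
  wg <- fit_wgmm_volume(b$test$volume, exclude_below = "otsu")
  fv <- gabor_transform(b$test$volume, pri$patch_dict$bank)
  small <- b$test$shape
  ctr <- centroid(small)
  small$vertices <- sweep(small$vertices, 2, ctr) * 0.75 +
    matrix(ctr, nrow(small$vertices), 3, byrow = TRUE)
  cfg <- pri$config
  cfg$lambda_smooth <- 0 # pure energy displacement
  pd <- pri$patch_dict
  pd$sigma_gate <- 1e-9 # keep every vertex active: this probes the energies
  pri$patch_dict <- pd
  st <- list(shape = small, iteration = 0L)
  r0 <- mean(sqrt(rowSums(sweep(small$vertices, 2, ctr)^2)))
  for (i in 1:5)
    st <- deform_step(st, b$test$volume, wg, pri$stats, pri$patch_dict, cfg,
                      feature_vol = fv)
  r5 <- mean(sqrt(rowSums(sweep(st$shape$vertices, 2, ctr)^2)))
  expect_gt(r5, r0 + 2) # strictly inflating toward the true radius
})

test_that("run_segmentation converges on an easy phantom", {
  b <- small_phantom_bundle()
  pri <- small_phantom_priors()
  seg <- run_segmentation(b$test$volume, pri, b$test$landmarks,
                          truth = b$test$shape)
  expect_s3_class(seg, "spssm_seg")
  expect_lte(seg$iterations, pri$config$max_iter)
  # sub-voxel mean accuracy: on a 24 mm blob at 1.5 mm voxels, a uniform
  # one-voxel surface error alone is ~12 % VOE
  expect_lt(voe(seg$mask, b$test$mask), 15)
  expect_equal(nrow(seg$log), seg$iterations)
  # gated vertices never move within an iteration
  expect_true(all(seg$log$frac_gated >= 0 & seg$log$frac_gated <= 1))
  # max_iter = 0 returns the initialized model untouched
  cfg0 <- pri$config; cfg0$max_iter <- 0L
  seg0 <- run_segmentation(b$test$volume, pri, b$test$landmarks, config = cfg0)
  expect_equal(seg0$iterations, 0L)
  expect_identical(seg0$shape$vertices, seg0$initial_shape$vertices)
})

test_that("segmentation results print, summarize and plot", {
  b <- small_phantom_bundle()
  pri <- small_phantom_priors()
  seg <- run_segmentation(b$test$volume, pri, b$test$landmarks)
  expect_output(print(seg), "spssm_seg")
  expect_output(summary(seg), "intensity band")
  pdf(NULL)
  expect_silent(plot(seg))
  dev.off()
  expect_identical(fitted(seg), seg$shape)
})

test_that("prior bundles survive a save/load round trip", {
  pri <- small_phantom_priors()
  b <- small_phantom_bundle()
  td <- withr::local_tempdir()
  save_priors(pri, td)
  back <- load_priors(td)
  expect_equal(back$dict$D_S, pri$dict$D_S, tolerance = 1e-9)
  expect_equal(back$stats$mu, pri$stats$mu, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$patch_dict$D, pri$patch_dict$D, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$patch_dict$sigma_gate, pri$patch_dict$sigma_gate,
               tolerance = 1e-12)
  # the reloaded bundle drives the same segmentation
  s1 <- run_segmentation(b$test$volume, pri, b$test$landmarks)
  s2 <- run_segmentation(b$test$volume, back, b$test$landmarks)
  expect_lt(max(abs(s1$shape$vertices - s2$shape$vertices)), 1e-6)
})

test_that("the command-line front end evaluates mask pairs", {
  cli <- system.file("exec", "spssm.R", package = "spssm")
  skip_if(cli == "", "installed CLI script not found")
  td <- withr::local_tempdir()
  a <- array(0, c(8, 8, 8)); a[2:6, 2:6, 2:6] <- 1
  b <- array(0, c(8, 8, 8)); b[3:7, 2:6, 2:6] <- 1
  write_volume(scalar_volume(a), file.path(td, "a.nii.gz"))
  write_volume(scalar_volume(b), file.path(td, "b.nii.gz"))
  out <- file.path(td, "rep.json")
  res <- system2("Rscript", c(cli, "evaluate", "--pred", file.path(td, "a.nii.gz"),
                              "--gold", file.path(td, "b.nii.gz"),
                              "--json", out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  js <- jsonlite::fromJSON(out)
  expect_equal(js$voe, voe(a, b), tolerance = 1e-8)
})

test_that("YAML configuration round-trips through read_config", {
  cfg <- spssm_config(alpha = 0.7, M = 25L, gate_quantile = 0.5,
                      gabor_frequencies = c(0.15, 0.3))
  p <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], p)
  back <- read_config(p)
  expect_equal(back$alpha, 0.7)
  expect_equal(back$M, 25L)
  expect_equal(back$gate_quantile, 0.5)
  expect_equal(back$gabor_frequencies, c(0.15, 0.3))
  expect_equal(back$lambda_smooth, cfg$lambda_smooth)
  expect_error(spssm_config(not_a_key = 1), "unknown config key")
})
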