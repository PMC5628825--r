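# Shared fixtures, all built in code.

# smallest closed mesh: a regular-ish tetrahedron
make_tetra <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  orient_outward(corr_shape(v, f))
}

# axis-aligned cube [0, a]^3 as a closed triangle mesh
make_cube <- function(a = 10) {
  v <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  orient_outward(corr_shape(v, f))
}

# linear-ramp volume I(x, y, z) = world x coordinate
ramp_volume <- function(dm = c(20, 20, 20), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(dm[1]) - 1) * spacing[1]
  scalar_volume(array(rep(xs, times = dm[2] * dm[3]), dm), spacing, origin)
}

sphere_shape <- function(subdiv = 2, radius = 1, centre = c(0, 0, 0)) {
  s <- icosphere(subdiv)
  s$vertices <- sweep(s$vertices * radius, 2, centre, "+")
  s
}

# small fast phantom study used by integration tests (cached per session)
.small_cache <- new.env(parent = emptyenv())
small_phantom_bundle <- function(jitter = 0, seed = 5L) {
  key <- paste0("b", jitter, "_", seed)
  if (is.null(.small_cache[[key]])) {
    spec <- phantom_spec(k = 5L, n_vertices = 162L, radius = 24,
                         grid_dim = c(48L, 48L, 48L), spacing = 1.5,
                         landmark_jitter = jitter, seed = seed)
    .small_cache[[key]] <- generate_training_bundle(spec)
  }
  .small_cache[[key]]
}
small_phantom_priors <- function(jitter = 0, seed = 5L) {
  key <- paste0("p", jitter, "_", seed)
  if (is.null(.small_cache[[key]])) {
    b <- small_phantom_bundle(jitter, seed)
    # patch and Gabor scale adapted to the small organ: the default 9x9x3
    # patch and f = 0.1 kernel (envelope ~5.6 voxels) span most of a 24 mm
    # radius blob, which leaves no interior to discriminate against
    # M = 21: the default +-15 mm profile reach would span the whole blob;
    # lambda_smooth = 0.1: Laplacian contraction scales with edge^2 / radius,
    # and the coarse 162-vertex mesh has edges ~28 % of the radius
    cfg <- spssm_config(max_patches_per_shape = 120L, n_atoms = 24L,
                        ksvd_iter = 5L, patch_shape = c(5L, 5L, 3L),
                        gabor_frequencies = c(0.2, 0.4), M = 21L,
                        lambda_smooth = 0.1)
    .small_cache[[key]] <- train_priors(b$train$shapes, b$train$volumes,
                                        b$landmark_indices, cfg)
  }
  .small_cache[[key]]
}
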