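# Synthetic phantom generator.
#
# Emulates the three external inputs the segmentation pipeline needs — a
# correspondence-consistent prior shape family, CT-like volumes with a
# five-mode intensity histogram (organ, an adjacent confounder organ with a
# close mean, fat/body, bone, background), and anatomically named landmarks —
# so every stage is testable without any data download.

#' Subdivided icosahedron (unit sphere mesh)
#'
#' @param subdiv number of 4-to-1 subdivisions (0 -> 12 vertices, 1 -> 42,
#'   2 -> 162, 3 -> 642, 4 -> 2562).
#' @return a [corr_shape()] of unit-radius vertices with outward faces.
#' @export
icosphere <- function(subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- p
      mid_cache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c3, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  orient_outward(corr_shape(v, f))
}

# Low-order real spherical-harmonic basis (l = 2, 3) evaluated on unit
# direction vectors; each mode is scaled to unit RMS over the given sample.
harmonic_basis <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  b <- cbind(
    3 * z^2 - 1, x * z, y * z, x^2 - y^2, x * y,
    z * (5 * z^2 - 3), x * (5 * z^2 - 1), y * (5 * z^2 - 1),
    z * (x^2 - y^2), x * y * z, x * (x^2 - 3 * y^2), y * (3 * x^2 - y^2))
  rms <- sqrt(colMeans(b^2))
  sweep(b, 2, rms, "/")
}

#' Phantom study specification
#'
#' Collects every tunable of the generator with defaults representing the
#' study conditions: a family of `k = 8` blob organs (642 vertices, mean
#' radius 60 mm, low-order harmonic mode variation), imaged on a 128^3 grid at
#' 1.5 mm with five intensity classes and additive noise. The confounder organ
#' sits adjacent to the organ with an intensity mean only `confounder_gap`
#' units away, emulating the spleen/stomach problem.
#'
#' @param k number of prior shapes.
#' @param n_vertices icosphere resolution (42/162/642/2562).
#' @param radius mean organ radius (mm).
#' @param mode_amplitude SD of each harmonic mode coefficient (relative
#'   radius units).
#' @param grid_dim,spacing volume geometry.
#' @param intensity data frame of class means/SDs/names (background, fat,
#'   organ, confounder, bone).
#' @param confounder_gap confounder mean minus organ mean (intensity units).
#' @param noise_sd additive Gaussian noise on top of the class draw.
#' @param landmark_jitter SD (mm) of the landmark placement error in
#'   generated test landmark files.
#' @param seed master seed; fixes everything downstream.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(k = 8L, n_vertices = 642L, radius = 60,
                         mode_amplitude = 0.03,
                         grid_dim = c(128L, 128L, 128L), spacing = 1.5,
                         intensity = NULL, confounder_gap = 20,
                         noise_sd = 4, landmark_jitter = 0, seed = 1L) {
  if (confounder_gap < 0) stopf("confounder gap must be >= 0")
  intensity <- intensity %||% data.frame(
    class = c("background", "fat", "organ", "confounder", "bone"),
    mean = c(20, 70, 120, 120 + confounder_gap, 220),
    sd = c(12, 22, 8, 10, 15))
  subdiv <- match(n_vertices, c(12L, 42L, 162L, 642L, 2562L)) - 1L
  if (is.na(subdiv)) stopf("n_vertices must be one of 12/42/162/642/2562")
  structure(list(k = k, n_vertices = n_vertices, subdiv = subdiv,
                 radius = radius, mode_amplitude = mode_amplitude,
                 grid_dim = as.integer(grid_dim), spacing = spacing,
                 intensity = intensity, confounder_gap = confounder_gap,
                 noise_sd = noise_sd, landmark_jitter = landmark_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# The seven landmark directions: pole, antipode and five equatorial/diagonal
# extremes, named after the canonical mark-point groups.
landmark_directions <- function() {
  rbind("Hepatic Dome" = c(0, 0, 1),
        "Right Lobe Anterior Segment" = c(1, 0, 0),
        "Right Lobe Tip" = c(0, 0, -1),
        "Right Lobe Posterior Segment" = c(-1, 0, 0),
        "Morrison Pouch" = c(0, 1, 0),
        "Porta Hepatis" = c(0, -1, 0),
        "Left Lobe Lateral Segment" = c(1, 1, 0) / sqrt(2))
}

#' Generate a correspondence-consistent prior shape family
#'
#' Each family member is the base icosphere radially perturbed by low-order
#' spherical-harmonic modes with per-shape Gaussian coefficients; shared
#' topology gives exact vertex correspondence. Landmarks are the vertices
#' nearest seven fixed parametric directions (pole, antipode, equatorial
#' extremes), identical indices across the family.
#'
#' @param spec a [phantom_spec()].
#' @return list: `shapes` (list of [corr_shape()]s, centred at the grid
#'   centre), `landmarks` (index-mode [landmark_set()]), `coefficients`.
#' @export
generate_shape_family <- function(spec) {
  base <- icosphere(spec$subdiv)
  dirs <- base$vertices
  B <- harmonic_basis(dirs)
  centre <- (spec$grid_dim - 1) * spec$spacing / 2
  coefs <- local_seed(spec$seed,
                      matrix(stats::rnorm(spec$k * ncol(B), 0, spec$mode_amplitude),
                             spec$k, ncol(B)))
  shapes <- lapply(seq_len(spec$k), function(i) {
    pert <- pmin(pmax(B %*% coefs[i, ], -0.3), 0.3)
    r <- spec$radius * (1 + pert)
    corr_shape(sweep(dirs * as.numeric(r), 2, centre, "+"), base$faces,
               family_id = sprintf("phantom-family-%d", spec$seed))
  })
  ld <- landmark_directions()
  idx <- apply(ld, 1, function(d) which.max(dirs %*% d))
  lm <- landmark_set(rownames(ld), "index", idx)
  list(shapes = shapes, landmarks = lm, coefficients = coefs)
}

# analytic ellipsoid voxel mask on the volume grid
ellipsoid_mask <- function(grid_dim, spacing, centre, semi) {
  xs <- (seq_len(grid_dim[1]) - 1) * spacing
  ys <- (seq_len(grid_dim[2]) - 1) * spacing
  zs <- (seq_len(grid_dim[3]) - 1) * spacing
  dx2 <- ((xs - centre[1]) / semi[1])^2
  dy2 <- ((ys - centre[2]) / semi[2])^2
  dz2 <- ((zs - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") < 1
}

#' Generate a CT-like phantom volume and gold mask for one shape
#'
#' Voxels inside the organ surface draw from the organ class; an adjacent
#' ellipsoidal confounder organ (mean `confounder_gap` above the organ), a
#' fat/body ellipsoid, a bone-like ellipsoid and an air-like background
#' complete the five histogram modes; independent Gaussian noise is added on
#' top. The gold mask is the voxelized organ.
#'
#' @param shape a [corr_shape()] from [generate_shape_family()].
#' @param spec a [phantom_spec()].
#' @param seed seed for this volume's noise (default derived from spec).
#' @return list: `volume` ([scalar_volume()]), `mask` ([scalar_volume()] 0/1).
#' @export
generate_ct_phantom <- function(shape, spec, seed = spec$seed) {
  dm <- spec$grid_dim; sp <- spec$spacing
  centre <- (dm - 1) * sp / 2
  grid <- scalar_volume(array(0, dm), rep(sp, 3), c(0, 0, 0))
  organ <- mesh_to_mask(shape, grid)$data > 0
  r <- spec$radius # surrounding anatomy scales with the organ
  body <- ellipsoid_mask(dm, sp, centre, r * c(1.47, 1.47, 1.53))
  # confounder: adjacent to the organ's +x extreme, intensity mean close by
  xmax <- max(shape$vertices[, 1])
  conf_c <- c(xmax + 0.27 * r + 3, centre[2], centre[3])
  conf <- ellipsoid_mask(dm, sp, conf_c, r * c(0.27, 0.33, 0.33)) & !organ
  bone <- ellipsoid_mask(dm, sp, centre - c(1.17 * r, 0, 0),
                         r * c(0.17, 0.17, 0.75)) & !organ
  it <- spec$intensity
  cls <- function(nm, col) it[[col]][match(nm, it$class)]
  mu <- array(cls("background", "mean"), dm)
  sd_ <- array(cls("background", "sd"), dm)
  assign_class <- function(mask, nm) {
    mu[mask] <<- cls(nm, "mean")
    sd_[mask] <<- cls(nm, "sd")
  }
  assign_class(body, "fat")
  assign_class(bone, "bone")
  assign_class(conf, "confounder")
  assign_class(organ, "organ")
  data <- local_seed(seed, {
    v <- mu + sd_ * stats::rnorm(length(mu))
    if (spec$noise_sd > 0) v <- v + stats::rnorm(length(mu), 0, spec$noise_sd)
    v
  })
  list(volume = scalar_volume(array(data, dm), rep(sp, 3), c(0, 0, 0)),
       mask = scalar_volume(array(as.numeric(organ), dm), rep(sp, 3), c(0, 0, 0)))
}

#' Generate a leave-one-out training bundle plus held-out test case
#'
#' Generates the full family and one phantom volume per member, holds the last
#' member out as the test case (with landmark world positions jittered by
#' `landmark_jitter` mm), and packages the rest for dictionary, profile and
#' patch training.
#'
#' @param spec a [phantom_spec()].
#' @param holdout index of the held-out member (default `spec$k`).
#' @return list with `train` (shapes, volumes), `test` (shape, volume, mask,
#'   landmarks as a world-mode [landmark_set()]), `landmark_indices`, `spec`.
#' @export
generate_training_bundle <- function(spec, holdout = spec$k) {
  fam <- generate_shape_family(spec)
  phantoms <- lapply(seq_len(spec$k), function(i)
    generate_ct_phantom(fam$shapes[[i]], spec,
                        seed = (spec$seed %% 2000000L) * 1000L + i))
  idx <- fam$landmarks$values
  test_shape <- fam$shapes[[holdout]]
  lm_world <- test_shape$vertices[idx, , drop = FALSE]
  lm_world <- local_seed(spec$seed + 7L,
                         lm_world + matrix(stats::rnorm(length(lm_world), 0,
                                                        spec$landmark_jitter),
                                           ncol = 3))
  train_ids <- setdiff(seq_len(spec$k), holdout)
  list(
    train = list(shapes = fam$shapes[train_ids],
                 volumes = lapply(phantoms[train_ids], `[[`, "volume")),
    test = list(shape = test_shape,
                volume = phantoms[[holdout]]$volume,
                mask = phantoms[[holdout]]$mask,
                landmarks = landmark_set(fam$landmarks$names, "world", lm_world)),
    landmark_indices = idx,
    spec = spec)
}
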