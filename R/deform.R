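# Iterative deformation driver.
#
# Per iteration and vertex the external force is
#   F = omega_norm * (E_edge + E_region)
# where the region term is the outward in-band walk, the edge term the
# combined profile-energy displacement, and omega_norm the sparse-matching
# gate weight normalized to [0, 1]. Displacements act along outward vertex
# normals, are capped at one profile step per iteration, and are followed by
# a Laplacian smoothing pass. A vertex whose Gabor patch is well reconstructed
# by the boundary dictionary is gated (weight 0) and stops moving; the run
# stops when every vertex is gated, when displacements plateau, or at the
# iteration cap.

#' Voxelize a closed mesh to a binary mask
#'
#' Voxel centres inside the surface become 1 (centre-inside rule), decided by
#' signed ray-crossing parity along z columns. The mesh must be watertight.
#'
#' @param shape a closed [corr_shape()].
#' @param grid_like a [scalar_volume()] defining the output grid.
#' @return a [scalar_volume()] with 0/1 data.
#' @export
mesh_to_mask <- function(shape, grid_like) {
  if (!is_closed_mesh(shape)) stopf("mesh_to_mask needs a closed (watertight) mesh")
  dm <- dim(grid_like$data)
  sp <- grid_like$spacing; org <- grid_like$origin
  for (attempt in 1:3) {
    # tiny deterministic ray offset avoids edge/vertex hits
    eps <- c(1e-6, 2e-6) * sp[1:2] * attempt
    cross <- ray_crossings(shape, dm, sp, org, eps)
    cnt <- tabulate(cross$col, nbins = dm[1] * dm[2])
    if (all(cnt %% 2L == 0L)) {
      return(scalar_volume(fill_parity(cross, dm, sp, org),
                           sp, org))
    }
  }
  stopf("ray parity failed: mesh appears non-watertight or degenerate")
}

# all (column id, z world) ray/triangle crossings for z-aligned rays through
# voxel centres offset by eps
ray_crossings <- function(shape, dm, sp, org, eps) {
  v <- shape$vertices; f <- shape$faces
  cols <- integer(0); zs <- numeric(0)
  acc_c <- vector("list", nrow(f)); acc_z <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(det) < 1e-12) next # projected-degenerate: parallel to the rays
    xr <- range(p1[1], p2[1], p3[1]); yr <- range(p1[2], p2[2], p3[2])
    ix <- seq.int(max(ceiling((xr[1] - org[1] - eps[1]) / sp[1]), 0),
                  min(floor((xr[2] - org[1] - eps[1]) / sp[1]), dm[1] - 1L))
    iy <- seq.int(max(ceiling((yr[1] - org[2] - eps[2]) / sp[2]), 0),
                  min(floor((yr[2] - org[2] - eps[2]) / sp[2]), dm[2] - 1L))
    if (!length(ix) || !length(iy)) next
    wx <- org[1] + ix * sp[1] + eps[1]
    wy <- org[2] + iy * sp[2] + eps[2]
    gx <- rep(wx, times = length(iy)); gy <- rep(wy, each = length(ix))
    u <- ((gx - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (gy - p1[2])) / det
    w <- ((p2[1] - p1[1]) * (gy - p1[2]) - (gx - p1[1]) * (p2[2] - p1[2])) / det
    hit <- u >= 0 & w >= 0 & (u + w) <= 1
    if (!any(hit)) next
    zhit <- p1[3] + u[hit] * (p2[3] - p1[3]) + w[hit] * (p3[3] - p1[3])
    colhit <- (rep(ix, times = length(iy)) + dm[1] * rep(iy, each = length(ix)))[hit] + 1L
    acc_c[[i]] <- colhit; acc_z[[i]] <- zhit
  }
  list(col = unlist(acc_c), z = unlist(acc_z))
}

fill_parity <- function(cross, dm, sp, org) {
  out <- array(0, dm)
  if (!length(cross$col)) return(out)
  o <- order(cross$col, cross$z)
  col <- cross$col[o]; z <- cross$z[o]
  ina <- seq(1, length(z), by = 2L); inb <- ina + 1L
  za <- z[ina]; zb <- z[inb]
  # voxel-centre indices strictly between each (za, zb) crossing pair
  k0 <- floor((za - org[3]) / sp[3]) + 1
  k1 <- ceiling((zb - org[3]) / sp[3]) - 1
  k0 <- pmax(k0, 0); k1 <- pmin(k1, dm[3] - 1L)
  keep <- k1 >= k0
  if (!any(keep)) return(out)
  k0 <- k0[keep]; k1 <- k1[keep]; colk <- col[ina][keep]
  lens <- k1 - k0 + 1
  zidx <- sequence(lens, from = k0)
  cidx <- rep(colk, lens)
  out[cidx + dm[1] * dm[2] * zidx] <- 1
  out
}

#' Laplacian mesh smoothing
#'
#' `v <- v + lambda * (mean of 1-ring neighbours - v)`, repeated `n_passes`
#' times. `lambda = 0` is the identity; planar meshes are invariant.
#'
#' @param shape a [corr_shape()] with faces.
#' @param lambda smoothing weight in `[0, 1]`.
#' @param n_passes number of passes.
#' @param neighbors optional precomputed edge structure (internal reuse).
#' @export
laplacian_smooth <- function(shape, lambda = 0.3, n_passes = 1L,
                             neighbors = NULL) {
  if (lambda == 0 || n_passes == 0L) return(shape)
  nb <- neighbors %||% smooth_structure(shape)
  v <- shape$vertices
  for (p in seq_len(n_passes)) {
    sums <- rowsum(v[nb$to, , drop = FALSE], nb$from, reorder = TRUE)
    means <- sums / nb$degree
    v <- v + lambda * (means - v)
  }
  shape$vertices <- v
  shape
}

# symmetric edge incidence used by laplacian_smooth
smooth_structure <- function(shape) {
  e <- unique(mesh_edges(shape$faces))
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  o <- order(from)
  from <- from[o]; to <- to[o]
  list(from = from, to = to,
       degree = as.numeric(table(factor(from, levels = seq_len(nrow(shape$vertices))))))
}

#' Default configuration of the deformation pipeline
#'
#' All method-level tunables in one place; any entry can be overridden by name.
#' Units: mm for lengths; samples for kernel bandwidths.
#'
#' @param ... overrides by name.
#' @export
spssm_config <- function(...) {
  cfg <- list(
    # sparse shape fit
    k1 = NULL,            # code sparsity; NULL -> ceiling(k / 2)
    k2 = 0L,              # landmark error sparsity (entries)
    lambda1 = 0.1, lambda2 = 10, sparse_method = "omp",
    # profiles and energies
    m_in = 5L, m_out = 5L,         # trained window: m = m_in + m_out + 1
    M = 31L,                       # search profile samples (k = M - m + 1)
    profile_step = 1.0,            # mm between profile samples
    kernel_bandwidth = NULL,       # samples; NULL -> m / 4
    alpha = 0.5,                   # statistical vs specific energy weight
    sigma_floor = 1e-3,
    # intensity model
    n_components = 5L, body_threshold = "otsu", n_bins = 512L,
    # sparse matching gate
    patch_shape = c(9L, 9L, 3L), n_atoms = 40L, patch_k1 = 4L,
    gabor_frequencies = c(0.1, 0.2),
    gabor_orientations = pi * c(0, 1, 2, 3) / 4,
    gate_quantile = 0.6, max_patches_per_shape = 250L,
    patch_train_volumes = 4L, ksvd_iter = 8L,
    # deformation
    lambda_smooth = 0.3, smooth_passes = 1L,
    max_iter = 50L, step_cap = NULL,  # NULL -> profile_step
    plateau_tol = 0.01, plateau_len = 3L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file of [spssm_config()] keys.
#' @export
read_config <- function(path) {
  do.call(spssm_config, yaml::read_yaml(path))
}

#' Train the prior-model bundle (dictionaries + statistics)
#'
#' Aligns the training family by GPA, stacks the shape/landmark dictionaries,
#' trains the per-vertex profile statistics against the training volumes, and
#' learns the Gabor patch dictionary with its gate threshold.
#'
#' @param shapes list of corresponding training [corr_shape()]s (image frame).
#' @param volumes list of matching [scalar_volume()]s.
#' @param landmark_indices integer landmark vertex indices (1-based).
#' @param config a [spssm_config()].
#' @return object of class `spssm_priors`: `dict`, `stats`, `patch_dict`,
#'   `gpa`, `config`.
#' @export
train_priors <- function(shapes, volumes, landmark_indices,
                         config = spssm_config()) {
  g <- gpa(shapes)
  dict <- build_dictionaries(g$aligned, landmark_indices)
  m <- config$m_in + config$m_out + 1L
  stats_ <- train_profile_stats(shapes, volumes, m_in = config$m_in,
                                m_out = config$m_out,
                                step = config$profile_step,
                                sigma_floor = config$sigma_floor,
                                bandwidth = config$kernel_bandwidth %||% (m / 4))
  bank <- gabor_bank(config$gabor_frequencies, config$gabor_orientations)
  # patches are pooled from an evenly spaced subset of the training pairs:
  # the Gabor transform dominates training cost and boundary texture is
  # homogeneous across members
  nv <- min(config$patch_train_volumes %||% length(volumes), length(volumes))
  sel <- unique(round(seq(1, length(volumes), length.out = nv)))
  pd <- build_patch_dictionary(volumes[sel], shapes[sel],
                               patch_shape = config$patch_shape,
                               n_atoms = config$n_atoms, k1 = config$patch_k1,
                               bank = bank, seed = config$seed,
                               max_patches_per_shape = config$max_patches_per_shape,
                               gate_quantile = config$gate_quantile,
                               n_iter = config$ksvd_iter)
  structure(list(dict = dict, stats = stats_, patch_dict = pd, gpa = g,
                 config = config),
            class = "spssm_priors")
}

#' @export
print.spssm_priors <- function(x, ...) {
  cat(sprintf("<spssm_priors> %d prior shapes x %d vertices; profile window %dx%d; %d patch atoms\n",
              x$dict$k, x$dict$n, nrow(x$stats$mu), ncol(x$stats$mu),
              ncol(x$patch_dict$D)))
  invisible(x)
}

#' One deformation iteration
#'
#' Samples profiles at the current vertices, combines the gated region and
#' edge displacements, moves vertices along their normals (capped), smooths,
#' and reports the new state. A state whose gates are all closed is returned
#' unchanged (gated vertices are fixed points).
#'
#' @param state list with at least `shape`; as returned by previous calls.
#' @param vol target [scalar_volume()].
#' @param wgmm a [fit_wgmm()] result for the organ band.
#' @param stats a [train_profile_stats()] result.
#' @param patch_dict a [build_patch_dictionary()] result.
#' @param config a [spssm_config()].
#' @param feature_vol optional precomputed [gabor_transform()] of `vol`.
#' @return updated state: `shape`, `iteration`, `omega`, `gated`,
#'   `displacement`, `converged`.
#' @export
deform_step <- function(state, vol, wgmm, stats, patch_dict,
                        config = spssm_config(), feature_vol = NULL) {
  shape <- state$shape
  n <- nrow(shape$vertices)
  feature_vol <- feature_vol %||% gabor_transform(vol, patch_dict$bank)
  # sparse-matching gate at current positions
  patches <- extract_boundary_patches(feature_vol, shape, patch_dict$patch_shape)
  L <- reconstruction_error(patches$patches, patch_dict)
  omega <- gate_weight(L, patch_dict$sigma_gate)
  state$omega <- omega
  state$gated <- omega == 0
  state$iteration <- (state$iteration %||% 0L) + 1L
  if (all_gated(omega)) {
    state$displacement <- numeric(n)
    state$converged <- TRUE
    return(state)
  }
  normals <- vertex_normals(shape)
  M <- config$M
  step <- config$profile_step
  prof <- sample_profiles(vol, shape$vertices, normals, M, step * (M - 1L))
  inband <- prof$values >= wgmm$G_L & prof$values <= wgmm$G_U
  disp_region <- region_energy_batch(inband, step, prof$center)
  ee <- edge_energy_batch(prof$values, stats, alpha = config$alpha)
  cap <- config$step_cap %||% step
  omega_norm <- omega / (max(omega) + 1e-12)
  disp <- omega_norm * (disp_region + ee$displacement)
  disp <- pmin(pmax(disp, -cap), cap)
  v <- shape$vertices + disp * normals
  # keep vertices inside the voxel lattice
  b <- volume_bounds(vol)
  for (a in 1:3) v[, a] <- pmin(pmax(v[, a], b[1, a]), b[2, a])
  shape$vertices <- v
  # gating zeroes the data-driven displacement only; the smoothness
  # regularizer still couples gated vertices to their neighbours, so a vertex
  # frozen off the boundary is dragged along and its gate can re-open on the
  # fresh image content (gates are re-evaluated every iteration)
  shape <- laplacian_smooth(shape, config$lambda_smooth, config$smooth_passes,
                            neighbors = state$smooth_nb)
  state$shape <- shape
  state$displacement <- disp
  state$converged <- FALSE
  state
}

#' Segment a volume with the sparse prior statistical shape model
#'
#' The full pipeline: fit the sparse code and transfer from the observed
#' landmarks, instantiate the model in image coordinates, fit the intensity
#' mixture, then iterate [deform_step()] until every vertex is gated, the
#' displacements plateau, or `max_iter` is reached. Deterministic given
#' `config$seed`.
#'
#' @param vol target [scalar_volume()].
#' @param priors a [train_priors()] bundle.
#' @param landmarks world-mode [landmark_set()] (or l x 3 matrix) in
#'   dictionary landmark order.
#' @param config a [spssm_config()]; defaults to the bundle's.
#' @param truth optional gold-standard [corr_shape()]; when given, the
#'   per-iteration mean vertex-to-truth surface distance is logged.
#' @return object of class `spssm_seg`: `shape` (final mesh), `mask`
#'   (binary [scalar_volume()]), `initial_shape`, `fit` (sparse landmark fit),
#'   `wgmm`, `log` (per-iteration data frame), `converged`, `iterations`,
#'   `config`.
#' @export
run_segmentation <- function(vol, priors, landmarks, config = NULL,
                             truth = NULL) {
  config <- config %||% priors$config
  fit <- fit_transfer(landmarks, priors$dict, k1 = config$k1, k2 = config$k2,
                      lambda1 = config$lambda1, lambda2 = config$lambda2,
                      method = config$sparse_method)
  model <- instantiate_model(priors$dict, fit)
  wg <- fit_wgmm_volume(vol, n_components = config$n_components,
                        exclude_below = config$body_threshold,
                        n_bins = config$n_bins, seed = config$seed)
  feature_vol <- gabor_transform(vol, priors$patch_dict$bank)
  state <- list(shape = model, iteration = 0L,
                smooth_nb = smooth_structure(model))
  log_rows <- list()
  plateau <- 0L
  converged <- FALSE
  truth_err <- function(s) {
    if (is.null(truth)) return(NA_real_)
    mean(nn_dist(s$vertices, truth$vertices))
  }
  while (state$iteration < config$max_iter) {
    state <- deform_step(state, vol, wg, priors$stats, priors$patch_dict,
                         config, feature_vol = feature_vol)
    mad_ <- mean(abs(state$displacement))
    log_rows[[state$iteration]] <- data.frame(
      iteration = state$iteration,
      mean_abs_disp = mad_,
      max_abs_disp = max(abs(state$displacement)),
      frac_gated = mean(state$gated),
      mean_surface_error = truth_err(state$shape))
    if (isTRUE(state$converged)) { converged <- TRUE; break }
    plateau <- if (mad_ < config$plateau_tol) plateau + 1L else 0L
    if (plateau >= config$plateau_len) { converged <- TRUE; break }
  }
  mask <- mesh_to_mask(state$shape, vol)
  structure(list(shape = state$shape, mask = mask, initial_shape = model,
                 fit = fit, wgmm = wg,
                 log = do.call(rbind, log_rows),
                 converged = converged, iterations = state$iteration,
                 all_gated = isTRUE(state$converged),
                 config = config),
            class = "spssm_seg")
}

#' @export
print.spssm_seg <- function(x, ...) {
  cat(sprintf("<spssm_seg> %d iterations (%s); %d vertices; %d voxels segmented\n",
              x$iterations,
              if (x$all_gated) "all gates closed"
              else if (x$converged) "plateau" else "iteration cap",
              nrow(x$shape$vertices), sum(x$mask$data)))
  invisible(x)
}

#' @export
summary.spssm_seg <- function(object, ...) {
  cat("Sparse prior statistical shape model segmentation\n")
  print(object)
  cat(sprintf("  organ intensity band: [%.1f, %.1f] (component mean %.1f)\n",
              object$wgmm$G_L, object$wgmm$G_U, object$wgmm$G_m))
  cat(sprintf("  sparse landmark fit: %d/%d atoms, residual %.3g\n",
              length(object$fit$support), length(object$fit$x),
              object$fit$residual))
  if (!is.null(object$log)) {
    cat("  last iterations:\n")
    print(utils::tail(object$log[, 1:4], 3), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.spssm_seg <- function(x, ...) {
  lg <- x$log
  if (is.null(lg) || !nrow(lg)) { warnf("nothing to plot"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(lg$iteration, lg$mean_abs_disp, type = "b", pch = 16,
       xlab = "iteration", ylab = "mean |displacement| (mm)",
       main = "deformation activity", ...)
  plot(lg$iteration, lg$frac_gated, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "iteration", ylab = "fraction gated",
       main = "sparse-matching gate", ...)
  invisible(x)
}

#' @export
fitted.spssm_seg <- function(object, ...) object$shape
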