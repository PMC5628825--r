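# Sparse-matching constraint: boundary texture in the Gabor domain.
#
# CT slices are filtered with a small 2-D Gabor bank; patches around training
# boundary vertices (in the filtered volume) are pooled and compressed into a
# K-SVD dictionary. At segmentation time each model vertex extracts the same
# size patch, sparse-codes it, and its reconstruction error decides whether
# the vertex keeps deforming (error above the gate) or is frozen (gated).

#' Build a 2-D Gabor filter bank
#'
#' Complex kernels `exp(-(x'^2 + y'^2) / (2 sigma^2)) exp(2 pi i f x')`, DC
#' removed, one per (frequency, orientation) pair. Envelope width follows the
#' wavelength (`sigma = 0.56 / f`).
#'
#' @param frequencies cycles/voxel (default 0.1, 0.2).
#' @param orientations radians (default 0, 45, 90, 135 degrees).
#' @return list of complex matrices (class `gabor_bank`).
#' @export
gabor_bank <- function(frequencies = c(0.1, 0.2),
                       orientations = pi * c(0, 1, 2, 3) / 4) {
  if (!length(frequencies) || !length(orientations)) stopf("empty Gabor bank")
  kernels <- list()
  for (f in frequencies) {
    sigma <- 0.56 / f
    half <- ceiling(2.5 * sigma)
    g <- seq(-half, half)
    for (th in orientations) {
      xr <- outer(g, g, function(x, y) x * cos(th) + y * sin(th))
      yr <- outer(g, g, function(x, y) -x * sin(th) + y * cos(th))
      env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
      kern <- env * exp(2i * pi * f * xr)
      kern <- kern - mean(kern) # zero-DC: constant images give zero response
      kernels[[length(kernels) + 1L]] <- kern
    }
  }
  structure(kernels, class = "gabor_bank",
            frequencies = frequencies, orientations = orientations)
}

#' Per-slice Gabor feature transform of a volume
#'
#' Filters every axial slice with each bank kernel (FFT convolution, circular
#' boundary) and combines the bank as the sum of the even-phase (real part)
#' responses: a signed, oriented band-pass edge feature. Constant volumes map
#' to zero (zero-DC kernels) and adding an intensity offset leaves the
#' response unchanged. The output shares the input grid.
#'
#' @param vol a [scalar_volume()].
#' @param bank a [gabor_bank()].
#' @return a [scalar_volume()] of feature responses.
#' @export
gabor_transform <- function(vol, bank) {
  if (!length(bank)) stopf("empty Gabor bank")
  dm <- dim(vol$data)
  nx <- dm[1]; ny <- dm[2]
  kf <- lapply(bank, function(k) {
    pk <- matrix(0 + 0i, nx, ny)
    kh <- dim(k)
    if (kh[1] > nx || kh[2] > ny) stopf("Gabor kernel larger than slice")
    pk[seq_len(kh[1]), seq_len(kh[2])] <- k
    # centre the kernel so the response is spatially aligned
    pk <- roll2(pk, -((kh[1] - 1L) %/% 2L), -((kh[2] - 1L) %/% 2L))
    stats::fft(pk)
  })
  out <- array(0, dm)
  for (z in seq_len(dm[3])) {
    F <- stats::fft(vol$data[, , z])
    acc <- matrix(0, nx, ny)
    for (i in seq_along(kf)) {
      acc <- acc + Re(stats::fft(F * kf[[i]], inverse = TRUE)) / (nx * ny)
    }
    out[, , z] <- acc
  }
  scalar_volume(out, vol$spacing, vol$origin)
}

# circular shift of a matrix by (dx, dy)
roll2 <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- ((seq_len(nx) - 1L - dx) %% nx) + 1L
  iy <- ((seq_len(ny) - 1L - dy) %% ny) + 1L
  m[ix, iy]
}

#' Extract vectorized patches around shape vertices
#'
#' One column per vertex: the `h x w x d` voxel neighbourhood of the feature
#' volume centred at the vertex's nearest voxel, vectorized in array order.
#' Patches touching the border are clamped to the volume and flagged.
#'
#' @param feature_vol a [scalar_volume()] (typically a [gabor_transform()]).
#' @param shape a [corr_shape()] inside the volume.
#' @param patch_shape integer length-3 (default `c(9, 9, 3)`).
#' @return list: `patches` (patch_len x n), `clamped` (logical n).
#' @export
extract_boundary_patches <- function(feature_vol, shape,
                                     patch_shape = c(9L, 9L, 3L)) {
  dm <- dim(feature_vol$data)
  ps <- as.integer(patch_shape)
  half <- (ps - 1L) %/% 2L
  ctr <- round(world_to_voxel(feature_vol, shape$vertices)) # 0-based
  offs <- as.matrix(expand.grid(x = seq_len(ps[1]) - 1L - half[1],
                                y = seq_len(ps[2]) - 1L - half[2],
                                z = seq_len(ps[3]) - 1L - half[3]))
  n <- nrow(ctr); plen <- prod(ps)
  # absolute 0-based voxel indices, clamped per axis
  clamped <- logical(n)
  idx <- matrix(0L, plen, n)
  ax <- vector("list", 3)
  for (a in 1:3) {
    ia <- outer(offs[, a], ctr[, a], "+")
    bad <- ia < 0L | ia > dm[a] - 1L
    clamped <- clamped | colSums(bad) > 0L
    ax[[a]] <- pmin(pmax(ia, 0L), dm[a] - 1L)
  }
  lin <- ax[[1]] + dm[1] * (ax[[2]] + dm[2] * ax[[3]]) + 1
  # as.vector: a plen x 3 index matrix must not trigger coordinate indexing
  patches <- matrix(feature_vol$data[as.vector(lin)], plen, n)
  list(patches = patches, clamped = clamped)
}

# Standardize patch columns: subtract the patch mean (the Gabor magnitude
# field has a positive DC offset everywhere, which carries no boundary
# information) and scale to unit l2 norm. Near-flat patches (residual norm
# below floor) are marked: a featureless patch carries no boundary evidence.
normalize_patches <- function(patches, floor = 1e-8) {
  patches <- sweep(patches, 2, colMeans(patches))
  nz <- sqrt(colSums(patches^2))
  flat <- nz < floor
  nz[flat] <- 1
  list(patches = sweep(patches, 2, nz, "/"), flat = flat)
}

#' Train the Gabor-domain boundary patch dictionary
#'
#' Gabor-transforms each training volume, pools patches at (a deterministic
#' subsample of) the training shapes' boundary vertices, l2-normalizes them,
#' and compresses the pool with [ksvd()]. The gate threshold is a quantile
#' (default 75th percentile) of the training patches' own reconstruction
#' errors: selective enough that only patches whose boundary texture is
#' centred reconstruct below it.
#'
#' @param training_volumes,training_shapes matched lists.
#' @param patch_shape patch voxels (default 9 x 9 x 3).
#' @param n_atoms dictionary size (default 40).
#' @param k1 pursuit sparsity (default 4).
#' @param bank a [gabor_bank()].
#' @param seed integer seed (K-SVD init and vertex subsampling).
#' @param max_patches_per_shape vertex subsample per training shape.
#' @param gate_quantile quantile of training errors used as the gate.
#' @param n_iter K-SVD iterations.
#' @return object of class `patch_dictionary`: `D`, `patch_shape`, `bank`,
#'   `sigma_gate`, `k1`, `train_errors`.
#' @export
build_patch_dictionary <- function(training_volumes, training_shapes,
                                   patch_shape = c(9L, 9L, 3L), n_atoms = 40L,
                                   k1 = 4L, bank = gabor_bank(), seed = 1L,
                                   max_patches_per_shape = 300L,
                                   gate_quantile = 0.75, n_iter = 8L) {
  stopifnot(length(training_volumes) == length(training_shapes))
  pools <- list()
  for (t in seq_along(training_volumes)) {
    fv <- gabor_transform(training_volumes[[t]], bank)
    s <- training_shapes[[t]]
    n <- nrow(s$vertices)
    pick <- if (n > max_patches_per_shape)
      local_seed(seed + t, sort(sample.int(n, max_patches_per_shape)))
    else seq_len(n)
    sub <- corr_shape(s$vertices[pick, , drop = FALSE])
    pools[[t]] <- extract_boundary_patches(fv, sub, patch_shape)$patches
  }
  Y <- do.call(cbind, pools)
  np <- normalize_patches(Y)
  Y <- np$patches[, !np$flat, drop = FALSE]
  if (ncol(Y) < n_atoms) n_atoms <- ncol(Y)
  kd <- ksvd(Y, n_atoms = n_atoms, k1 = k1, n_iter = n_iter, seed = seed)
  errs <- omp_pursuit(kd$D, Y, k1)$residual
  structure(list(D = kd$D, patch_shape = as.integer(patch_shape), bank = bank,
                 sigma_gate = as.numeric(stats::quantile(errs, gate_quantile)),
                 k1 = k1, train_errors = errs),
            class = "patch_dictionary")
}

#' @export
print.patch_dictionary <- function(x, ...) {
  cat(sprintf("<patch_dictionary> %d atoms of %s voxels, gate sigma %.4g\n",
              ncol(x$D), paste(x$patch_shape, collapse = "x"), x$sigma_gate))
  invisible(x)
}

#' Sparse reconstruction error of a patch
#'
#' `L_gabor = ||y - D x||_2` with `x` from orthogonal pursuit at sparsity
#' `k1`. The patch is l2-normalized first (atoms are unit norm), so the error
#' measures texture match, not contrast magnitude; a near-flat patch scores
#' the maximal error 1.
#'
#' @param patch numeric vector (patch_len) or matrix (patch_len x n).
#' @param dict a [build_patch_dictionary()] result (or any unit-norm matrix).
#' @param k1 pursuit sparsity (defaults to the dictionary's).
#' @return numeric vector of errors (>= 0).
#' @export
reconstruction_error <- function(patch, dict, k1 = NULL) {
  D <- if (inherits(dict, "patch_dictionary")) dict$D else as.matrix(dict)
  k1 <- k1 %||% (if (inherits(dict, "patch_dictionary")) dict$k1 else 1L)
  Y <- as.matrix(patch)
  np <- normalize_patches(Y)
  errs <- omp_pursuit(D, np$patches, k1)$residual
  errs[np$flat] <- 1
  errs
}

#' Gate weight from a reconstruction error
#'
#' Zero when the error is at or below the gate threshold (the vertex has
#' found boundary-like texture and freezes); otherwise the raw error, which
#' keeps the vertex deforming with strength proportional to its mismatch.
#'
#' @param L_gabor reconstruction error(s).
#' @param sigma_gate gate threshold (> 0).
#' @return weight(s) `omega_external`.
#' @export
gate_weight <- function(L_gabor, sigma_gate) {
  if (sigma_gate <= 0) stopf("sigma_gate must be positive")
  ifelse(L_gabor <= sigma_gate, 0, L_gabor)
}

#' Are all vertices gated?
#'
#' The global stop condition: TRUE iff every per-vertex weight is zero.
#' @param weights numeric vector of gate weights.
#' @export
all_gated <- function(weights) {
  if (!length(weights)) stopf("empty weight vector: stop condition undefined")
  all(weights == 0)
}
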