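# Volume- and surface-agreement metrics between binary masks, following the
# liver-challenge conventions: volumetric overlap error, relative volume
# difference, and the symmetric surface distances (mean / RMS / maximum)
# measured between border voxels in anisotropy-aware mm.

as_mask_array <- function(m) {
  a <- if (inherits(m, "scalar_volume")) m$data else as.array(m)
  if (length(dim(a)) != 3L) stopf("mask must be a 3-D array")
  a != 0
}

#' Volumetric overlap error (percent)
#'
#' `VOE = 100 (1 - |A intersect B| / |A union B|)`.
#' @param a,b binary masks (3-D arrays or [scalar_volume()]s on one grid).
#' @export
voe <- function(a, b) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stopf("masks must share a grid")
  if (!any(a) || !any(b)) stopf("empty mask")
  100 * (1 - sum(a & b) / sum(a | b))
}

#' Relative volume difference (percent, signed)
#'
#' `RVD = 100 (|A| - |B|) / |B|`; report `abs()` for scoring.
#' @inheritParams voe
#' @export
rvd <- function(a, b) {
  a <- as_mask_array(a); b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stopf("masks must share a grid")
  if (!any(b)) stopf("empty reference mask")
  100 * (sum(a) - sum(b)) / sum(b)
}

# Exact nearest-neighbour distances (mm) from lattice points `a` to lattice
# point set `b` on a shared grid. Integer displacements are scanned in order
# of physical length, so a point's first hit is its exact nearest neighbour;
# box completeness bounds guarantee exactness, and distant stragglers fall
# back to the dense BLAS path.
lattice_nn_dist <- function(a, b, dm, spacing) {
  a <- matrix(as.integer(a), ncol = 3); b <- matrix(as.integer(b), ncol = 3)
  occ <- array(FALSE, dm)
  occ[b + 1L] <- TRUE
  n <- nrow(a)
  best <- rep(NA_real_, n)
  unresolved <- seq_len(n)
  for (lv in c(2L, 6L, 14L)) {
    if (!length(unresolved)) break
    g <- -lv:lv
    offs <- as.matrix(expand.grid(x = g, y = g, z = g))
    dmm <- sqrt(colSums((t(offs) * spacing)^2))
    # within the box, first-hit order is exact only up to this radius
    safe <- lv * min(spacing)
    keep <- dmm <= safe
    offs <- offs[keep, , drop = FALSE]; dmm <- dmm[keep]
    o <- order(dmm)
    offs <- offs[o, , drop = FALSE]; dmm <- dmm[o]
    au <- a[unresolved, , drop = FALSE]
    hit_d <- rep(NA_real_, nrow(au))
    todo <- seq_len(nrow(au))
    for (i in seq_len(nrow(offs))) {
      if (!length(todo)) break
      p <- au[todo, , drop = FALSE] +
        matrix(offs[i, ], length(todo), 3, byrow = TRUE)
      ok <- p[, 1] >= 0L & p[, 1] < dm[1] & p[, 2] >= 0L & p[, 2] < dm[2] &
        p[, 3] >= 0L & p[, 3] < dm[3]
      if (any(ok)) {
        lin <- p[ok, 1] + dm[1] * (p[ok, 2] + dm[2] * p[ok, 3]) + 1
        found <- occ[lin]
        if (any(found)) {
          got <- todo[ok][found]
          hit_d[got] <- dmm[i]
          todo <- setdiff(todo, got)
        }
      }
    }
    best[unresolved[!is.na(hit_d)]] <- hit_d[!is.na(hit_d)]
    unresolved <- unresolved[is.na(hit_d)]
  }
  if (length(unresolved)) {
    pa <- sweep(a[unresolved, , drop = FALSE], 2, spacing, "*")
    pb <- sweep(b, 2, spacing, "*")
    best[unresolved] <- nn_dist(pa, pb)
  }
  best
}

# Border voxels of a mask under 6-connectivity (mask minus its erosion);
# returns an n x 3 matrix of 0-based voxel indices.
border_voxels <- function(mask) {
  m <- as_mask_array(mask)
  dm <- dim(m)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  er <- core &
    pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  which(m & !er, arr.ind = TRUE) - 1L
}

#' Symmetric surface distances between two masks (mm)
#'
#' Border voxels (6-connectivity erosion difference) of each mask are taken as
#' surface points at their anisotropic mm positions; distances are exact
#' nearest-neighbour Euclidean distances, symmetrized by pooling both
#' directions. ASSD is the mean, RMSSSD the root mean square, MSSD the
#' maximum.
#'
#' @inheritParams voe
#' @param spacing per-axis voxel size in mm.
#' @return list: `assd`, `rmsssd`, `mssd`, `d_ab`, `d_ba`.
#' @export
surface_distances <- function(a, b, spacing = c(1, 1, 1)) {
  am <- as_mask_array(a); bm <- as_mask_array(b)
  if (!identical(dim(am), dim(bm))) stopf("masks must share a grid")
  if (!any(am) || !any(bm)) stopf("empty mask")
  ba <- border_voxels(am); bb <- border_voxels(bm)
  d_ab <- lattice_nn_dist(ba, bb, dim(am), spacing)
  d_ba <- lattice_nn_dist(bb, ba, dim(am), spacing)
  all_d <- c(d_ab, d_ba)
  list(assd = mean(all_d), rmsssd = sqrt(mean(all_d^2)), mssd = max(all_d),
       d_ab = d_ab, d_ba = d_ba)
}

#' Challenge-style score for a metric value
#'
#' `score = max(0, 100 - 25 |value| / ref)`: 100 for perfect agreement, 75 at
#' the reference error, clamped at 0. The default references follow the
#' liver-challenge convention and are configuration constants, not measured
#' quantities.
#'
#' @param value metric value (same units as `ref`).
#' @param ref reference error for that metric.
#' @export
seg_score <- function(value, ref) {
  s <- pmax(0, 100 - 25 * abs(value) / ref) # pmax drops names; restore them
  names(s) <- names(value)
  s
}

#' Default scoring reference errors
#' @export
score_references <- function() {
  c(voe = 6.4, rvd = 4.7, assd = 1.0, rmsssd = 1.8, mssd = 19.0)
}

#' Full metrics report for a predicted vs gold mask pair
#'
#' @param pred,gold binary masks on one grid.
#' @param spacing per-axis voxel size (mm).
#' @param refs named scoring references (see [score_references()]).
#' @return object of class `metrics_report` with the five metrics (RVD both
#'   signed and absolute), per-metric scores and the total score.
#' @export
evaluate_segmentation <- function(pred, gold, spacing = c(1, 1, 1),
                                  refs = score_references()) {
  v <- voe(pred, gold)
  r <- rvd(pred, gold)
  sd_ <- surface_distances(pred, gold, spacing)
  vals <- c(voe = v, rvd = abs(r), assd = sd_$assd, rmsssd = sd_$rmsssd,
            mssd = sd_$mssd)
  scores <- seg_score(vals, refs[names(vals)])
  structure(list(voe = v, rvd_signed = r, rvd_abs = abs(r),
                 assd = sd_$assd, rmsssd = sd_$rmsssd, mssd = sd_$mssd,
                 scores = scores, total_score = mean(scores),
                 refs = refs),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  VOE    %7.2f %%   (score %5.1f)\n", x$voe, x$scores["voe"]))
  cat(sprintf("  RVD    %+7.2f %%   (score %5.1f, |RVD| = %.2f)\n",
              x$rvd_signed, x$scores["rvd"], x$rvd_abs))
  cat(sprintf("  ASSD   %7.2f mm  (score %5.1f)\n", x$assd, x$scores["assd"]))
  cat(sprintf("  RMSSSD %7.2f mm  (score %5.1f)\n", x$rmsssd, x$scores["rmsssd"]))
  cat(sprintf("  MSSD   %7.2f mm  (score %5.1f)\n", x$mssd, x$scores["mssd"]))
  cat(sprintf("  total score %5.1f\n", x$total_score))
  invisible(x)
}
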