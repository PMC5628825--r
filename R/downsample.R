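# Correspondence-establishing decimation of a prior family.
#
# The reference (first) shape is decimated by quadric edge collapse; each
# surviving vertex is then mapped to every other family member as the closest
# point on that member's surface after a rigid (similarity) ICP pre-alignment.
# All outputs share the reference topology, which establishes the vertex
# correspondence the Procrustes and dictionary stages require.

# --- quadric edge-collapse decimation ---------------------------------------

# Fundamental error quadrics: one 4x4 K = p p^T per face plane, accumulated
# on the face's vertices.
vertex_quadrics <- function(v, f) {
  fn <- cbind(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  nrm <- cbind(fn[, 2] * fn[, 6] - fn[, 3] * fn[, 5],
               fn[, 3] * fn[, 4] - fn[, 1] * fn[, 6],
               fn[, 1] * fn[, 5] - fn[, 2] * fn[, 4])
  len <- row_norms(nrm); len[len == 0] <- 1
  nrm <- nrm / len
  d <- -rowSums(nrm * v[f[, 1], , drop = FALSE])
  q <- vector("list", nrow(v))
  zero <- matrix(0, 4, 4)
  for (j in seq_len(nrow(v))) q[[j]] <- zero
  for (i in seq_len(nrow(f))) {
    p <- c(nrm[i, ], d[i])
    k <- tcrossprod(p)
    for (c in 1:3) {
      j <- f[i, c]
      q[[j]] <- q[[j]] + k
    }
  }
  q
}

collapse_cost <- function(q, v1, v2) {
  # optimal position: solve the regularized quadric system; fall back to the
  # best of (v1, v2, midpoint)
  a <- q[1:3, 1:3]; b <- -q[1:3, 4]
  pos <- tryCatch({
    if (abs(det(a)) > 1e-10 * max(abs(a), 1)^3) solve(a, b) else NULL
  }, error = function(e) NULL)
  cand <- rbind(pos, v1, v2, (v1 + v2) / 2)
  h <- cbind(cand, 1)
  costs <- rowSums((h %*% q) * h)
  i <- which.min(costs)
  list(cost = costs[i], pos = cand[i, ])
}

# Decimate a closed triangle mesh to n_target vertices (greedy min-cost
# quadric edge collapse, deterministic).
decimate_mesh <- function(shape, n_target) {
  v <- shape$vertices
  f <- shape$faces
  n <- nrow(v)
  if (n_target >= n) return(shape)
  q <- vertex_quadrics(v, f)
  alive <- rep(TRUE, n)
  n_alive <- n
  edge_tab <- unique(mesh_edges(f))
  costs <- numeric(nrow(edge_tab))
  posns <- matrix(0, nrow(edge_tab), 3)
  for (i in seq_len(nrow(edge_tab))) {
    cc <- collapse_cost(q[[edge_tab[i, 1]]] + q[[edge_tab[i, 2]]],
                        v[edge_tab[i, 1], ], v[edge_tab[i, 2], ])
    costs[i] <- cc$cost; posns[i, ] <- cc$pos
  }
  while (n_alive > n_target && nrow(edge_tab) > 0L) {
    i <- which.min(costs)
    u <- edge_tab[i, 1]; w <- edge_tab[i, 2]
    v[u, ] <- posns[i, ]
    alive[w] <- FALSE
    n_alive <- n_alive - 1L
    q[[u]] <- q[[u]] + q[[w]]
    # rewire faces and edges from w to u
    f[f == w] <- u
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    f <- f[!degen, , drop = FALSE]
    edge_tab[edge_tab == w] <- u
    e1 <- pmin(edge_tab[, 1], edge_tab[, 2])
    e2 <- pmax(edge_tab[, 1], edge_tab[, 2])
    edge_tab <- cbind(e1, e2)
    keep <- e1 != e2 & !duplicated(paste(e1, e2))
    edge_tab <- edge_tab[keep, , drop = FALSE]
    costs <- costs[keep]; posns <- posns[keep, , drop = FALSE]
    touched <- which(edge_tab[, 1] == u | edge_tab[, 2] == u)
    for (j in touched) {
      cc <- collapse_cost(q[[edge_tab[j, 1]]] + q[[edge_tab[j, 2]]],
                          v[edge_tab[j, 1], ], v[edge_tab[j, 2], ])
      costs[j] <- cc$cost; posns[j, ] <- cc$pos
    }
  }
  idx <- which(alive)
  remap <- integer(n); remap[idx] <- seq_along(idx)
  corr_shape(v[idx, , drop = FALSE],
             matrix(remap[f], ncol = 3), shape$family_id)
}

# --- closest point on a triangle mesh ---------------------------------------

# Closest point on a single mesh from one query point; vectorized across all
# triangles (Ericson's barycentric clamping).
closest_point_on_mesh <- function(query, shape) {
  v <- shape$vertices; f <- shape$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  ap <- matrix(query, nrow(a), 3, byrow = TRUE) - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
  denom <- d00 * d11 - d01 * d01
  denom[denom == 0] <- 1e-300
  vbar <- (d11 * d1 - d01 * d2) / denom
  wbar <- (d00 * d2 - d01 * d1) / denom
  vbar <- pmin(pmax(vbar, 0), 1)
  wbar <- pmin(pmax(wbar, 0), 1)
  over <- vbar + wbar > 1
  s <- vbar[over] + wbar[over]
  vbar[over] <- vbar[over] / s
  wbar[over] <- wbar[over] / s
  # clamped barycentric projection is approximate on edge regions; refine the
  # winning triangle exactly below
  cand <- a + vbar * ab + wbar * ac
  d2q <- rowSums((cand - matrix(query, nrow(a), 3, byrow = TRUE))^2)
  shortlist <- order(d2q)[seq_len(min(8L, length(d2q)))]
  best <- NULL; bestd <- Inf
  for (ti in shortlist) {
    tri <- rbind(v[f[ti, 1], ], v[f[ti, 2], ], v[f[ti, 3], ])
    cp <- closest_point_on_triangle(query, tri)
    dd <- sum((cp - query)^2)
    if (dd < bestd) { bestd <- dd; best <- cp }
  }
  best
}

# Exact closest point on one triangle (Ericson, Real-Time Collision Detection).
closest_point_on_triangle <- function(p, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c3 <- tri[3, ]
  ab <- b - a; ac <- c3 - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c3
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c3)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c3 - b))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

# Rigid (similarity) ICP of moving onto fixed, nearest-vertex correspondences,
# centroid/scale initialization. Deterministic.
icp_align <- function(fixed, moving, max_iter = 15L, tol = 1e-8) {
  vf <- fixed$vertices; vm <- moving$vertices
  s0 <- shape_size(vf) / shape_size(vm)
  tf <- similarity_transform(s0, diag(3), centroid(vf) - s0 * centroid(vm))
  prev <- Inf
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(tf, vm)
    nb2 <- rowSums(vf * vf)
    d2 <- outer(rowSums(cur * cur), nb2, "+") - 2 * tcrossprod(cur, vf)
    idx <- max.col(-d2, ties.method = "first")
    err <- mean(pmax(d2[cbind(seq_len(nrow(d2)), idx)], 0))
    res <- align_pair(vf[idx, , drop = FALSE], vm)
    tf <- res$transform
    if (abs(prev - err) < tol * (1 + err)) break
    prev <- err
  }
  tf
}

#' Correspondence-preserving downsampling of a prior shape family
#'
#' Decimates the first family member to `n_target` vertices (quadric edge
#' collapse), then maps each surviving vertex onto every other member as the
#' nearest surface point after pairwise rigid-ICP alignment. All outputs share
#' the decimated reference topology, so vertex `j` denotes the same anatomical
#' location throughout the family.
#'
#' @param shapes list of closed [corr_shape()]s.
#' @param n_target vertex count of the outputs (`4 <= n_target <= min n`).
#' @return list of [corr_shape()]s with exactly `n_target` vertices each and a
#'   shared `family_id`.
#' @export
downsample_with_correspondence <- function(shapes, n_target) {
  if (!length(shapes)) stopf("no shapes given")
  for (s in shapes) if (!is_closed_mesh(s)) stopf("all input meshes must be closed")
  nmin <- min(vapply(shapes, function(s) nrow(s$vertices), 1L))
  if (n_target > nmin) stopf("n_target (%d) exceeds smallest input (%d vertices)",
                             n_target, nmin)
  if (n_target < 4L) stopf("n_target must be at least 4")
  fam <- shapes[[1]]$family_id %||% "downsampled-family"
  ref <- decimate_mesh(shapes[[1]], n_target)
  ref$family_id <- fam
  # every output vertex -- including the first member's -- is the closest
  # surface point on that member, so identical members map identically and
  # all outputs lie on their own surfaces
  out <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    tf <- if (i == 1L) similarity_transform()
          else icp_align(shapes[[1]], shapes[[i]])
    inv <- invert_transform(tf)
    aligned <- apply_transform(tf, shapes[[i]])
    mapped <- t(vapply(seq_len(nrow(ref$vertices)), function(j)
      closest_point_on_mesh(ref$vertices[j, ], aligned), numeric(3)))
    out[[i]] <- corr_shape(apply_transform(inv, mapped), ref$faces, fam)
  }
  out
}
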