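# Boundary (edge) energy: intensity profiles are sampled along outward vertex
# normals; a trained per-vertex statistical term and an untrained inner/outer
# contrast term are slid along the profile and combined into a displacement
# vote.

#' Sample an intensity profile along a vertex normal
#'
#' Sample `i` (of `m`) sits at `x + ((i-1)/(m-1) - 1/2) * L * u`, with `u` the
#' outward unit normal and `L` the total physical profile length, so samples
#' run inside -> outside from `-L/2` to `+L/2` and the middle sample (odd `m`)
#' is the vertex itself. Trilinear interpolation; out-of-volume samples take
#' the nearest in-volume value and are flagged.
#'
#' @param vol a [scalar_volume()].
#' @param vertex length-3 world point (mm).
#' @param normal length-3 outward unit normal.
#' @param m number of samples.
#' @param L total profile length (mm).
#' @return object of class `intensity_profile`: `values`, `positions`,
#'   `step` (mm), `center` (index), `clamped`.
#' @export
sample_profile <- function(vol, vertex, normal, m, L) {
  if (L <= 0) stopf("profile length must be positive")
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-6) stopf("normal must be unit length")
  b <- volume_bounds(vol)
  if (any(vertex < b[1, ] - L) || any(vertex > b[2, ] + L))
    stopf("vertex lies outside the volume bounding box by more than L")
  off <- ((seq_len(m) - 1) / (m - 1) - 0.5) * L
  pts <- matrix(vertex, m, 3, byrow = TRUE) + outer(off, normal)
  sm <- vol_sample(vol, pts)
  structure(list(values = sm$values, positions = pts, step = L / (m - 1),
                 center = (m + 1L) %/% 2L, clamped = sm$clamped),
            class = "intensity_profile")
}

# Batch profile sampling: M x n matrix of intensities for all vertices at once.
sample_profiles <- function(vol, vertices, normals, m, L) {
  n <- nrow(vertices)
  off <- ((seq_len(m) - 1) / (m - 1) - 0.5) * L
  # points stacked sample-major within vertex
  pts <- vertices[rep(seq_len(n), each = m), , drop = FALSE] +
    normals[rep(seq_len(n), each = m), , drop = FALSE] * rep(off, n)
  sm <- vol_sample(vol, pts)
  list(values = matrix(sm$values, nrow = m),
       clamped = matrix(sm$clamped, nrow = m),
       step = L / (m - 1), center = (m + 1L) %/% 2L)
}

#' Train per-vertex profile statistics on a correspondence family
#'
#' For every training pair (shape, volume), an `m = m_in + m_out + 1` sample
#' profile is taken at each vertex along its outward normal; `mu_ij` and
#' `sigma_ij` (sample SD, `z - 1` denominator, floored at `sigma_floor`) are
#' accumulated over the `z` training pairs.
#'
#' @param training_shapes list of [corr_shape()]s in image coordinates.
#' @param training_volumes list of matching [scalar_volume()]s.
#' @param m_in,m_out samples inside/outside the boundary (defaults 5 and 5).
#' @param step physical sample spacing (mm), default 1.
#' @param sigma_floor lower bound on sigma_ij.
#' @param bandwidth Gaussian kernel bandwidth (samples) stored for the
#'   statistical energy; default `m / 4`.
#' @return object of class `profile_stats`: `mu`, `sigma` (m x n), `m_in`,
#'   `m_out`, `step`, `bandwidth`, `z`.
#' @export
train_profile_stats <- function(training_shapes, training_volumes,
                                m_in = 5L, m_out = 5L, step = 1,
                                sigma_floor = 1e-3, bandwidth = NULL) {
  z <- length(training_shapes)
  if (z < 2L) stopf("profile statistics need at least 2 training pairs")
  if (length(training_volumes) != z) stopf("shapes/volumes length mismatch")
  m <- m_in + m_out + 1L
  L <- step * (m - 1L)
  n <- nrow(training_shapes[[1]]$vertices)
  acc <- array(0, c(m, n, z))
  for (t in seq_len(z)) {
    s <- training_shapes[[t]]
    if (nrow(s$vertices) != n) stopf("training shapes must share a vertex count")
    nrm <- vertex_normals(s)
    acc[, , t] <- sample_profiles(training_volumes[[t]], s$vertices, nrm, m, L)$values
  }
  mu <- apply(acc, c(1, 2), mean)
  sigma <- apply(acc, c(1, 2), stats::sd)
  sigma <- pmax(sigma, sigma_floor)
  structure(list(mu = mu, sigma = sigma, m_in = m_in, m_out = m_out,
                 step = step, bandwidth = bandwidth %||% (m / 4), z = z),
            class = "profile_stats")
}

#' Statistical feature energy along a long profile
#'
#' Slides the trained `m`-sample template over an `M`-sample profile. Window
#' `t` (of `k = M - m + 1`) scores
#' `P_t = sum_i K(|i - 1 - m_in|) N(p_{t+i-1}; mu_i, sigma_i)` with a Gaussian
#' kernel centred on the window's boundary sample; scores are min-max
#' normalized then scaled to sum 1 (uniform when degenerate).
#'
#' @param profile numeric M-sample profile (inside -> outside).
#' @param mu,sigma length-m trained means/SDs for this vertex.
#' @param m_in,m_out window geometry.
#' @param bandwidth kernel bandwidth in samples.
#' @return length-k non-negative vector summing to 1.
#' @export
statistics_energy <- function(profile, mu, sigma, m_in, m_out,
                              bandwidth = (m_in + m_out + 1) / 4) {
  m <- m_in + m_out + 1L
  M <- length(profile)
  k <- M - m + 1L
  if (k < 1L) stopf("profile shorter than the trained window")
  kw <- gauss_kernel(abs(seq_len(m) - (m_in + 1L)), bandwidth)
  p <- vapply(seq_len(k), function(t) {
    w <- profile[t:(t + m - 1L)]
    sum(kw * stats::dnorm(w, mu, sigma))
  }, 1.0)
  normalize_energy(p)
}

#' Specific (contrast) feature energy along a long profile
#'
#' For each window position the kernel-weighted absolute inner/outer mean
#' difference `f1` and the inner/outer spread difference `f2` are computed;
#' each is min-max normalized over the window positions, summed, and scaled to
#' sum 1. A constant profile degenerates to the uniform vector.
#'
#' @inheritParams statistics_energy
#' @return length-k non-negative vector summing to 1.
#' @export
specific_energy <- function(profile, m_in, m_out,
                            bandwidth = (m_in + m_out + 1) / 4) {
  m <- m_in + m_out + 1L
  M <- length(profile)
  k <- M - m + 1L
  if (k < 1L) stopf("profile shorter than the window")
  kw <- gauss_kernel(abs(seq_len(m) - (m_in + 1L)), bandwidth)
  f1 <- numeric(k); f2 <- numeric(k)
  for (t in seq_len(k)) {
    w <- profile[t:(t + m - 1L)]
    inner <- w[seq_len(m_in)]
    outer_ <- w[(m_in + 2L):m]
    p_in <- sum(kw[seq_len(m_in)] * inner) / m_in
    p_out <- sum(kw[(m_in + 2L):m] * outer_) / m_out
    f1[t] <- abs(p_in - p_out)
    v_in <- if (m_in > 1L) sum((inner - p_in)^2) / (m_in - 1L) else 0
    v_out <- if (m_out > 1L) sum((outer_ - p_out)^2) / (m_out - 1L) else 0
    f2[t] <- v_out - v_in
  }
  normalize_energy(minmax01(f1) + minmax01(f2))
}

minmax01 <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

# min-max then sum-to-one; all-equal input becomes uniform.
normalize_energy <- function(p) {
  v <- minmax01(p)
  s <- sum(v)
  if (s <= 0) return(rep(1 / length(p), length(p)))
  v / s
}

#' Combine statistical and specific energies into a displacement vote
#'
#' `i* = argmax_i alpha * E_statistics(i) + beta_w * E_specific(i)` with
#' `alpha + beta_w = 1`; ties are broken towards the window nearest the
#' profile centre.
#'
#' @param e_statistics,e_specific length-k energy vectors.
#' @param alpha,beta_w non-negative weights summing to 1.
#' @return list: `offset` (window index i*), `score` (the maximum).
#' @export
edge_energy <- function(e_statistics, e_specific, alpha = 0.5,
                        beta_w = 1 - alpha) {
  if (length(e_statistics) != length(e_specific))
    stopf("energy vectors must have equal length")
  if (alpha < 0 || beta_w < 0 || abs(alpha + beta_w - 1) > 1e-9)
    stopf("alpha and beta_w must be non-negative and sum to 1")
  comb <- alpha * e_statistics + beta_w * e_specific
  mx <- max(comb)
  cand <- which(comb >= mx - 1e-15)
  ctr <- (length(comb) + 1) / 2
  off <- cand[which.min(abs(cand - ctr))]
  list(offset = off, score = mx)
}

# Vectorized boundary energy across vertices.
# P: M x n profile matrix; stats: profile_stats; returns list with the signed
# displacement (mm) per vertex and the combined k x n energy matrix.
edge_energy_batch <- function(P, stats, alpha = 0.5, beta_w = 1 - alpha) {
  m <- stats$m_in + stats$m_out + 1L
  M <- nrow(P); n <- ncol(P)
  k <- M - m + 1L
  kw <- gauss_kernel(abs(seq_len(m) - (stats$m_in + 1L)), stats$bandwidth)
  est <- matrix(0, k, n)
  f1 <- matrix(0, k, n); f2 <- matrix(0, k, n)
  idx_in <- seq_len(stats$m_in)
  idx_out <- (stats$m_in + 2L):m
  for (t in seq_len(k)) {
    W <- P[t:(t + m - 1L), , drop = FALSE]
    est[t, ] <- colSums(kw * stats::dnorm(W, stats$mu, stats$sigma))
    p_in <- colSums(kw[idx_in] * W[idx_in, , drop = FALSE]) / stats$m_in
    p_out <- colSums(kw[idx_out] * W[idx_out, , drop = FALSE]) / stats$m_out
    f1[t, ] <- abs(p_in - p_out)
    v_in <- colSums((W[idx_in, , drop = FALSE] -
                       rep(p_in, each = stats$m_in))^2) / max(stats$m_in - 1L, 1L)
    v_out <- colSums((W[idx_out, , drop = FALSE] -
                        rep(p_out, each = stats$m_out))^2) / max(stats$m_out - 1L, 1L)
    f2[t, ] <- v_out - v_in
  }
  norm_cols <- function(mat) apply(mat, 2, normalize_energy)
  mm_cols <- function(mat) apply(mat, 2, minmax01)
  esp <- norm_cols(mm_cols(f1) + mm_cols(f2))
  est <- norm_cols(est)
  comb <- alpha * est + beta_w * esp
  ctr_win <- (k + 1) / 2
  offs <- apply(comb, 2, function(v) {
    cand <- which(v >= max(v) - 1e-15)
    cand[which.min(abs(cand - ctr_win))]
  })
  center <- (M + 1L) %/% 2L
  disp <- ((offs + stats$m_in) - center) * stats$step
  list(displacement = disp, offset = offs, combined = comb,
       score = comb[cbind(offs, seq_len(n))])
}
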