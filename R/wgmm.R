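# Intensity (region) energy: a five-component weighted Gaussian mixture of
# the image histogram identifies the organ intensity band, and a profile walk
# proposes the outward displacement that keeps samples inside that band.

#' Fit a weighted Gaussian mixture to intensity samples
#'
#' EM with quantile-spread initialization (deterministic given `seed`, which
#' only matters for the optional jitter-free restarts). Components are sorted
#' by mean. The organ ("liver") component is the one with maximal peak height
#' `h_i = w_i / sigma_i` (ties broken towards the larger weight), and the
#' organ band is `[mu_m - 1.5 sigma_m, mu_m + 1.5 sigma_m]`.
#'
#' @param x numeric samples (or bin centres when `weights` given).
#' @param n_components number of Gaussians (default 5).
#' @param weights optional non-negative sample weights (histogram counts).
#' @param seed integer seed (kept for interface stability; the fit is
#'   deterministic).
#' @param max_iter,tol EM controls.
#' @param sigma_floor lower bound on component SDs; collapsing components are
#'   floored and flagged.
#' @return object of class `wgmm_fit`: `weights`, `means`, `sds`, `heights`,
#'   `organ_component`, `G_m`, `G_L`, `G_U`, `loglik`, `floored`.
#' @export
fit_wgmm <- function(x, n_components = 5L, weights = NULL, seed = 1L,
                     max_iter = 300L, tol = 1e-9, sigma_floor = 1e-3) {
  x <- as.numeric(x)
  if (is.null(weights)) weights <- rep(1, length(x))
  ok <- is.finite(x) & weights > 0
  x <- x[ok]; weights <- weights[ok]
  if (length(unique(x)) < n_components)
    stopf("need at least %d distinct intensity values", n_components)
  g <- n_components
  wsum <- sum(weights)
  # quantile-spread init
  ord <- order(x)
  cw <- cumsum(weights[ord]) / wsum
  qs <- vapply((2 * seq_len(g) - 1) / (2 * g),
               function(p) x[ord][which.min(abs(cw - p))], 1.0)
  mu <- as.numeric(qs)
  xbar <- sum(weights * x) / wsum
  sd_all <- sqrt(sum(weights * (x - xbar)^2) / wsum)
  sg <- rep(max(sd_all / g, sigma_floor), g)
  pw <- rep(1 / g, g)
  floored <- FALSE
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(g), function(i) pw[i] * stats::dnorm(x, mu[i], sg[i]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(weights * log(tot))
    resp <- dens / tot
    nk <- colSums(weights * resp)
    nk[nk <= 0] <- .Machine$double.xmin
    pw <- nk / wsum
    mu <- colSums(weights * resp * x) / nk
    for (i in seq_len(g)) {
      v <- sum(weights * resp[, i] * (x - mu[i])^2) / nk[i]
      si <- sqrt(v)
      if (!is.finite(si) || si < sigma_floor) { si <- sigma_floor; floored <- TRUE }
      sg[i] <- si
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
    ll_prev <- ll
  }
  o <- order(mu)
  pw <- pw[o]; mu <- mu[o]; sg <- sg[o]
  h <- pw / sg
  best <- which(h == max(h))
  if (length(best) > 1L) best <- best[which.max(pw[best])]
  structure(list(weights = pw, means = mu, sds = sg, heights = h,
                 organ_component = best, G_m = mu[best],
                 G_L = mu[best] - 1.5 * sg[best],
                 G_U = mu[best] + 1.5 * sg[best],
                 loglik = ll, floored = floored),
            class = "wgmm_fit")
}

#' @export
print.wgmm_fit <- function(x, ...) {
  cat(sprintf("<wgmm_fit> %d components; organ component %d: mean %.2f, band [%.2f, %.2f]\n",
              length(x$means), x$organ_component, x$G_m, x$G_L, x$G_U))
  df <- data.frame(weight = round(x$weights, 4), mean = round(x$means, 3),
                   sd = round(x$sds, 3), height = signif(x$heights, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit the mixture to a volume histogram
#'
#' Bins the volume intensities (optionally restricted to a body mask by an
#' intensity threshold) and runs the weighted EM on the bin centres. With
#' `exclude_below = "otsu"` the threshold is Otsu's on the full histogram,
#' which removes the air background before the five tissue modes are fit.
#'
#' @param vol a [scalar_volume()].
#' @param n_components number of Gaussians.
#' @param exclude_below numeric threshold, `"otsu"`, or `NULL` (use all voxels).
#' @param n_bins histogram resolution (default 512).
#' @param ... passed to [fit_wgmm()].
#' @export
fit_wgmm_volume <- function(vol, n_components = 5L, exclude_below = NULL,
                            n_bins = 512L, ...) {
  x <- as.numeric(vol$data)
  if (identical(exclude_below, "otsu")) exclude_below <- otsu_threshold(x)
  if (!is.null(exclude_below)) x <- x[x > exclude_below]
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- hist(x, breaks = br, plot = FALSE)
  keep <- h$counts > 0
  fit_wgmm(h$mids[keep], n_components = n_components, weights = h$counts[keep], ...)
}

# Otsu's threshold on a numeric vector (maximal between-class variance).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  h <- hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[length(m0)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, length(p))
  bc[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bc)]
}

#' Region (intensity) energy: outward in-band walk along a profile
#'
#' Walks the profile from the centre sample outward while both the current and
#' the next sample stay inside the organ band `[G_L, G_U]`, accumulating one
#' step per move; an out-of-band centre gives 0. The result is the outward
#' displacement (mm) the intensity term proposes.
#'
#' @param intensities profile samples ordered inside -> outside.
#' @param step physical sample spacing (mm).
#' @param G_L,G_U organ intensity band.
#' @param center index of the centre (vertex) sample; default the middle.
#' @return displacement in mm (>= 0).
#' @export
region_energy <- function(intensities, step, G_L, G_U,
                          center = (length(intensities) + 1L) %/% 2L) {
  p <- as.numeric(intensities)
  inb <- p >= G_L & p <= G_U
  if (!inb[center]) return(0)
  i <- center
  disp <- 0
  while (i < length(p) && inb[i] && inb[i + 1L]) {
    disp <- disp + step
    i <- i + 1L
  }
  disp
}

# Vectorized region energy across vertices: `inband` is an M x n logical
# matrix of in-band flags; returns mm displacement per vertex.
region_energy_batch <- function(inband, step, center) {
  out_part <- inband[center:nrow(inband), , drop = FALSE]
  cp <- apply(out_part, 2, cumprod)
  if (is.null(dim(cp))) cp <- matrix(cp, nrow = 1L)
  runs <- colSums(cp)
  disp <- pmax(runs - 1, 0) * step
  disp[!inband[center, ]] <- 0
  disp
}
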