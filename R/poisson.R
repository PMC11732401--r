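#' Estimate oriented point-cloud normals
#'
#' Normals from local PCA over `k` nearest neighbours (the eigenvector of
#' the smallest covariance eigenvalue), oriented outward from the cloud
#' centroid.
#'
#' @param cloud `p x 3` matrix, mm.
#' @param k neighbourhood size.
#' @return `p x 3` matrix of unit normals.
#' @export
estimate_normals <- function(cloud, k = 12L) {
  cloud <- as.matrix(cloud)
  p <- nrow(cloud)
  if (p < k) stop("estimate_normals: fewer points than k")
  nn <- cpp_knn(cloud, cloud, as.integer(k))$idx
  cen <- colMeans(cloud)
  normals <- matrix(0, p, 3)
  for (i in seq_len(p)) {
    nb <- cloud[nn[i, ], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    n <- ev$vectors[, 3]
    if (sum(n * (cloud[i, ] - cen)) < 0) n <- -n
    normals[i, ] <- n
  }
  normals
}

#' Remove far outliers from a point cloud
#'
#' Emulates manual pre-cleaning of intra-chamber ultrasound clouds: points
#' whose distance from the cloud centroid deviates from the mean radius by
#' more than `n_sd` standard deviations are dropped.
#'
#' @param cloud `p x 3` matrix, mm.
#' @param n_sd deviation threshold in standard deviations (default 3).
#' @return the filtered cloud.
#' @export
trim_cloud_outliers <- function(cloud, n_sd = 3) {
  cloud <- as.matrix(cloud)
  r <- sqrt(rowSums(sweep(cloud, 2, colMeans(cloud))^2))
  keep <- abs(r - mean(r)) <= n_sd * stats::sd(r)
  cloud[keep, , drop = FALSE]
}

#' Poisson surface reconstruction from an oriented point cloud
#'
#' Global surface fit by solving the Poisson equation for the indicator
#' function: oriented normals are splatted onto a regular grid as a vector
#' field `V`, the indicator `chi` solves `laplacian(chi) = div(V)`
#' spectrally (FFT on the padded grid), and the surface is extracted as the
#' level set of `chi` at the average indicator value over the samples,
#' using marching tetrahedra. Only the largest connected component is kept
#' and no smoothing is applied to the result.
#'
#' @param cloud `p x 3` matrix, mm; `p >= 500`.
#' @param depth grid resolution exponent; the grid has `2^depth` cells per
#'   axis over the padded bounding cube (default 6, i.e. 64).
#' @param k_normals neighbourhood size for normal estimation.
#' @return a closed [surface_mesh] oriented outward.
#' @export
poisson_reconstruct <- function(cloud, depth = 6L, k_normals = 12L) {
  cloud <- as.matrix(cloud)
  if (nrow(cloud) < 500L)
    stop("poisson_reconstruct: needs >= 500 points, got ", nrow(cloud))
  if (qr(sweep(cloud, 2, colMeans(cloud)))$rank < 3L)
    stop("poisson_reconstruct: degenerate cloud (rank < 3)")
  normals <- estimate_normals(cloud, k = k_normals)
  n <- as.integer(2^depth)
  lo <- apply(cloud, 2, min)
  hi <- apply(cloud, 2, max)
  side <- max(hi - lo) * 1.5          # padding keeps the periodic wrap away
  origin <- (lo + hi) / 2 - side / 2
  h <- side / (n - 1)
  # trilinear splat of normals into three grids
  g <- array(0, c(n, n, n, 3))
  rel <- sweep(cloud, 2, origin) / h
  i0 <- pmin(pmax(floor(rel), 0), n - 2)
  fr <- rel - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
           (if (dy) fr[, 2] else 1 - fr[, 2]) *
           (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    for (d in 1:3) {
      lin <- idx[, 1] + n * (idx[, 2] - 1) + n * n * (idx[, 3] - 1) +
        n^3 * (d - 1)
      acc <- tapply(wgt * normals[, d], lin, sum)
      g[as.integer(names(acc))] <- g[as.integer(names(acc))] + as.numeric(acc)
    }
  }
  # spectral solve: chi_hat = div(V)_hat / (-|k|^2), with Gaussian smoothing
  freq <- 2 * pi * c(0:(n %/% 2), -(n - n %/% 2 - 1):-1) / (n * h)
  kx <- array(rep(freq, times = n * n), c(n, n, n))
  ky <- aperm(kx, c(2, 1, 3))
  kz <- aperm(kx, c(3, 2, 1))
  k2 <- kx^2 + ky^2 + kz^2
  sigma <- 1.5 * h
  gauss <- exp(-0.5 * sigma^2 * k2)
  div_hat <- (1i * kx) * stats::fft(g[, , , 1]) +
             (1i * ky) * stats::fft(g[, , , 2]) +
             (1i * kz) * stats::fft(g[, , , 3])
  div_hat <- div_hat * gauss
  chi_hat <- div_hat / (-pmax(k2, 1e-12))
  chi_hat[1, 1, 1] <- 0
  chi <- Re(stats::fft(chi_hat, inverse = TRUE)) / n^3
  # iso level: average indicator value at the samples
  iso <- mean(trilinear_interp(chi, origin, h, cloud))
  surf <- cpp_marching_tets(as.numeric(chi), n, n, n, origin, h, iso)
  mesh <- surface_mesh(surf$vertices, surf$faces + 1L, validate = FALSE)
  mesh <- orient_consistent(largest_component(mesh, warn = FALSE))
  if (!is_closed_mesh(mesh))
    warning("poisson_reconstruct: extracted surface is not closed")
  orient_outward(mesh)
}

trilinear_interp <- function(vol, origin, h, pts) {
  n <- dim(vol)[1]
  rel <- sweep(as.matrix(pts), 2, origin) / h
  i0 <- pmin(pmax(floor(rel), 0), n - 2)
  fr <- rel - i0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
           (if (dy) fr[, 2] else 1 - fr[, 2]) *
           (if (dz) fr[, 3] else 1 - fr[, 3])
    out <- out + wgt * vol[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                                 i0[, 3] + dz + 1)]
  }
  out
}
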