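# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the package's accelerated implementations.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

sphere_mesh <- function(r = 30, subdiv = 4L) {
  fixture(paste0("sphere_", r, "_", subdiv), function() {
    m <- atriamesh:::icosphere(subdiv)
    m$vertices <- m$vertices * r
    m
  })
}

sphere_contours <- function() {
  fixture("sphere_cs", function()
    slice_to_contours(sphere_mesh(30, 4L),
                      phantom_spec("sphere", size = 30, in_plane_noise_sd = 0)))
}

cube_mesh <- function(side = 10) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  orient_outward(surface_mesh(v, f))
}

square_contour <- function(side = 10, z = 0) {
  contour(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
          slice_pose(c(0, 0, z), c(1, 0, 0), c(0, 1, 0), "axial"))
}

two_square_set <- function() {
  contour_set(list(square_contour(10, 0), square_contour(10, 8)),
              lid_low = c(5, 5, -4), lid_high = c(5, 5, 12))
}

circle_contour <- function(r, z = 0, n = 96, center = c(0, 0)) {
  th <- 2 * pi * (0:(n - 1)) / n
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
          slice_pose(c(0, 0, z), c(1, 0, 0), c(0, 1, 0), "axial"))
}

# independent point-to-triangle distance (plane projection + edge clamping;
# different construction from the C++ kernel)
bf_point_tri_dist <- function(p, a, b, c) {
  seg <- function(p, a, b) {
    ab <- b - a
    t0 <- sum((p - a) * ab) / sum(ab^2)
    t0 <- min(max(t0, 0), 1)
    sqrt(sum((p - a - t0 * ab)^2))
  }
  n <- pracma_cross(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-300) return(min(seg(p, a, b), seg(p, b, c), seg(p, a, c)))
  n <- n / nn
  q <- p - sum((p - a) * n) * n
  # barycentric test of the projected point
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0^2); d01 <- sum(v0 * v1); d11 <- sum(v1^2)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01^2
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(abs(sum((p - a) * n)))
  min(seg(p, a, b), seg(p, b, c), seg(p, a, c))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

bf_mesh_distance <- function(mesh, pts) {
  apply(pts, 1, function(p) {
    min(vapply(seq_len(nrow(mesh$faces)), function(f) {
      tri <- mesh$faces[f, ]
      bf_point_tri_dist(p, mesh$vertices[tri[1], ], mesh$vertices[tri[2], ],
                        mesh$vertices[tri[3], ])
    }, 0))
  })
}

# exhaustive greedy farthest-point sampling oracle
bf_fps <- function(cand, n, seed_index = 1L) {
  sel <- seed_index
  d <- as.matrix(stats::dist(cand))
  mind <- d[, seed_index]
  while (length(sel) < n) {
    best <- which(mind == max(mind))[1]
    sel <- c(sel, best)
    mind <- pmin(mind, d[, best])
  }
  sel
}

# average ranks computed from scratch (independent of base rank())
bf_avg_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

# Mann-Whitney two-sided p by full enumeration of group assignments
bf_mann_whitney <- function(g1, g0) {
  pooled <- c(g1, g0)
  m <- length(g1)
  n <- length(g0)
  u_of <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  u_obs <- u_of(g1, g0)
  combos <- utils::combn(length(pooled), m)
  dev_obs <- abs(u_obs - m * n / 2)
  cnt <- 0L
  for (k in seq_len(ncol(combos))) {
    x <- pooled[combos[, k]]
    y <- pooled[-combos[, k]]
    if (abs(u_of(x, y) - m * n / 2) >= dev_obs - 1e-12) cnt <- cnt + 1L
  }
  list(U = u_obs, p = cnt / ncol(combos))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rotation_axis <- function(axis, deg) {
  a <- deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

rot_angle_deg <- function(R) {
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}
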