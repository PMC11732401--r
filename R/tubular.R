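#' Initial ruled-surface (tubular) mesh from a contour stack
#'
#' Resamples every axial contour to `K` equally spaced vertices, rotates
#' each contour's vertex indexing to minimise the total rung length to its
#' predecessor (twist minimisation), connects consecutive contours with the
#' triangle pairs `(C_j^i, C_j^{i+1}, C_{j+1}^i)` and
#' `(C_{j+1}^i, C_{j+1}^{i+1}, C_j^{i+1})`, and closes the surface with
#' triangle fans from the extreme contours to the lid points. The result is
#' a closed, consistently oriented genus-0 mesh with `K * J + 2` vertices
#' and `2K(J-1) + 2K` faces for `J` contours.
#'
#' @param cs a [contour_set].
#' @param K vertices per contour, `>= 3`.
#' @return a [surface_mesh] oriented outward.
#' @export
build_tubular_mesh <- function(cs, K) {
  if (K < 3L) stop("build_tubular_mesh: K must be >= 3")
  axis <- cs$stack_axis
  z <- vapply(cs$contours, stack_coordinate, 0, axis = axis)
  if (any(diff(z) <= 0)) stop("build_tubular_mesh: contours out of order")
  J <- length(cs$contours)
  rings <- lapply(cs$contours, function(ct) to_global(resample_contour(ct, K)))
  # twist minimisation: rotate indexing of ring j to minimise total rung
  # length to ring j-1
  for (j in seq_len(J)[-1]) {
    prev <- rings[[j - 1L]]
    cur <- rings[[j]]
    best_off <- 0L
    best_len <- Inf
    for (off in 0:(K - 1L)) {
      idx <- ((seq_len(K) - 1L + off) %% K) + 1L
      len <- sum(sqrt(rowSums((cur[idx, , drop = FALSE] - prev)^2)))
      if (len < best_len) { best_len <- len; best_off <- off }
    }
    if (best_off > 0L) {
      idx <- ((seq_len(K) - 1L + best_off) %% K) + 1L
      rings[[j]] <- cur[idx, , drop = FALSE]
    }
  }
  verts <- do.call(rbind, rings)
  verts <- rbind(verts, cs$lid_low, cs$lid_high)
  i_low <- K * J + 1L
  i_high <- K * J + 2L
  faces <- vector("list", J + 1L)
  for (j in seq_len(J - 1L)) {
    a <- (j - 1L) * K + seq_len(K)            # ring j
    b <- j * K + seq_len(K)                   # ring j+1
    an <- a[c(2:K, 1L)]                       # C_j^{i+1}
    bn <- b[c(2:K, 1L)]                       # C_{j+1}^{i+1}
    faces[[j]] <- rbind(cbind(a, an, b), cbind(b, an, bn))
  }
  r1 <- seq_len(K)
  rJ <- (J - 1L) * K + seq_len(K)
  faces[[J]] <- cbind(i_low, r1[c(2:K, 1L)], r1)            # bottom fan
  faces[[J + 1L]] <- cbind(i_high, rJ, rJ[c(2:K, 1L)])      # top fan
  f <- do.call(rbind, faces)
  dimnames(f) <- NULL
  mesh <- surface_mesh(verts, f)
  orient_outward(mesh)
}

#' Farthest point sampling of attractor points along contours
#'
#' Greedy coverage: starting from the candidate at `seed_index`, repeatedly
#' adds the candidate maximising its minimum Euclidean distance to the
#' already selected points; ties break to the lowest candidate index. The
#' candidate pool is the densely resampled contour vertices.
#'
#' @param cs a [contour_set].
#' @param n number of attractors, `>= 1`.
#' @param seed_index 1-based index of the starting candidate (default 1).
#' @param dense_K candidate points per contour (default 200).
#' @return list with `points` (`n x 3`, mm), `source` (contour index per
#'   attractor) of class `attractor_set`.
#' @export
sample_attractors <- function(cs, n, seed_index = 1L, dense_K = 200L) {
  cand <- do.call(rbind, lapply(cs$contours, function(ct)
    to_global(resample_contour(ct, dense_K))))
  src <- rep(seq_along(cs$contours), each = dense_K)
  sel <- farthest_point_sampling(cand, n, seed_index)
  structure(list(points = cand[sel, , drop = FALSE], source = src[sel],
                 index = sel), class = "attractor_set")
}

#' Greedy farthest point sampling over a candidate matrix
#' @param candidates `c x 3` matrix.
#' @param n points to select.
#' @param seed_index starting candidate (1-based).
#' @return integer vector of selected candidate indices, length `n`.
#' @export
farthest_point_sampling <- function(candidates, n, seed_index = 1L) {
  nc <- nrow(candidates)
  if (n < 1L) stop("farthest_point_sampling: n must be >= 1")
  if (n > nc) stop("farthest_point_sampling: n (", n,
                   ") exceeds candidate count (", nc, ")")
  sel <- integer(n)
  sel[1L] <- seed_index
  mind <- sqrt(colSums((t(candidates) - candidates[seed_index, ])^2))
  if (n > 1L) for (k in 2:n) {
    best <- which.max(mind)  # which.max returns the first (lowest) index on ties
    sel[k] <- best
    d <- sqrt(colSums((t(candidates) - candidates[best, ])^2))
    mind <- pmin(mind, d)
  }
  sel
}

#' Bounded attractor pull targets
#'
#' For each attractor `Q_i`, finds the closest point `P_i` on the mesh
#' surface and the bounded step target
#' `Q_i' = P_i + beta * (Q_i - P_i) / ||Q_i - P_i||`. When
#' `||Q_i - P_i|| <= beta` the attractor is captured: `Q_i' = Q_i`.
#'
#' @param mesh a [surface_mesh].
#' @param attractors an `attractor_set` (or `n x 3` matrix).
#' @param beta step length, mm; `beta = 0` gives `Q_i' = P_i`.
#' @return list with `P` (closest surface points) and `Q_prime` (targets).
#' @export
attractor_targets <- function(mesh, attractors, beta) {
  q <- if (inherits(attractors, "attractor_set")) attractors$points
       else matrix(as.numeric(attractors), ncol = 3)
  cl <- mesh_closest_points(mesh, q)
  p <- cl$points
  d <- cl$dist
  qp <- q
  far <- d > beta & d > 0
  if (any(far)) {
    dir <- (q[far, , drop = FALSE] - p[far, , drop = FALSE]) / d[far]
    qp[far, ] <- p[far, , drop = FALSE] + beta * dir
  }
  # captured attractors (d <= beta) keep Q_i' = Q_i
  list(P = p, Q_prime = qp, dist = d)
}
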