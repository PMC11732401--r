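#' Laplacian (umbrella) mesh smoothing
#'
#' Per iteration each vertex moves towards the centroid of its edge
#' neighbours: `p_i <- p_i + w * (mean_{j in N_i} p_j - p_i)`, updated
#' simultaneously for all vertices. Topology is unchanged.
#'
#' @param mesh a [surface_mesh].
#' @param w step weight in `(0, 1]`.
#' @param iters number of iterations.
#' @return the smoothed [surface_mesh].
#' @export
laplacian_smooth <- function(mesh, w, iters = 1L) {
  if (w <= 0 || w > 1) stop("laplacian_smooth: w must be in (0, 1]")
  if (iters < 1L) return(mesh)
  a <- vertex_adjacency(mesh)
  deg <- Matrix::rowSums(a)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  for (k in seq_len(iters)) {
    nb_mean <- as.matrix(a %*% v) / deg
    v <- v + w * (nb_mean - v)
  }
  mesh$vertices <- v
  mesh
}

#' Midpoint (linear) subdivision
#'
#' Splits every triangle into four by inserting edge midpoints; the surface
#' is unchanged as a point set (no shrinkage), the mesh is refined 4x in
#' face count.
#'
#' @param mesh a [surface_mesh].
#' @return the subdivided [surface_mesh].
#' @export
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ue <- !duplicated(key)
  eid <- match(key, key[ue])            # edge id per (face,corner) edge
  mids <- (v[e[ue, 1], , drop = FALSE] + v[e[ue, 2], , drop = FALSE]) / 2
  m <- nrow(f)
  m12 <- n + eid[seq_len(m)]
  m23 <- n + eid[m + seq_len(m)]
  m31 <- n + eid[2 * m + seq_len(m)]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(m12, f[, 2], m23),
              cbind(m31, m23, f[, 3]),
              cbind(m12, m23, m31))
  surface_mesh(rbind(v, mids), f2, validate = FALSE)
}

#' Quadric-error-metric decimation
#'
#' Edge-collapse simplification to approximately `target_faces` faces,
#' rejecting collapses that would break manifoldness or flip face normals.
#'
#' @param mesh a closed manifold [surface_mesh].
#' @param target_faces target face count.
#' @return the decimated [surface_mesh], re-oriented outward when closed.
#' @export
decimate_mesh <- function(mesh, target_faces) {
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  out <- cpp_decimate_qem(mesh$vertices, mesh$faces - 1L,
                          as.integer(target_faces))
  m <- surface_mesh(out$vertices, out$faces + 1L, validate = FALSE)
  if (is_closed_mesh(m)) m <- orient_outward(m)
  m
}
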