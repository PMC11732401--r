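#' Triangular surface mesh
#'
#' Container for an oriented triangular surface mesh in millimetres. Vertices
#' are an `n x 3` numeric matrix, faces an `m x 3` integer matrix of 1-based
#' vertex indices (file formats with 0-based indexing are converted on I/O).
#'
#' @param vertices numeric matrix, `n x 3`, coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param validate check index validity and edge-manifoldness.
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (validate) validate_mesh(m)
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (anyNA(v)) stop("mesh vertices contain NA")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, ", nrow(v), "]")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("degenerate face (repeated vertex index)")
    cnt <- edge_use_counts(mesh)
    if (any(cnt > 2L)) stop("mesh is not edge-manifold (an edge is shared by >2 faces)")
  }
  invisible(mesh)
}

# undirected edge keys and use counts
edge_use_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Number of boundary edges of a mesh
#'
#' An interior edge of an oriented manifold mesh is used by exactly two
#' faces; boundary edges by one.
#' @param mesh a [surface_mesh].
#' @return integer count of boundary edges.
#' @export
boundary_edge_count <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0L)
  sum(edge_use_counts(mesh) == 1L)
}

#' Is the mesh closed (watertight)?
#' @param mesh a [surface_mesh].
#' @return `TRUE` if the mesh has no boundary edges.
#' @export
is_closed_mesh <- function(mesh) boundary_edge_count(mesh) == 0L

#' Is the mesh consistently oriented?
#'
#' In a consistently oriented mesh every interior edge is traversed once in
#' each direction.
#' @param mesh a [surface_mesh].
#' @return logical.
#' @export
is_oriented_mesh <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(TRUE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  !anyDuplicated(key)
}

#' Euler characteristic V - E + F
#' @param mesh a [surface_mesh].
#' @return integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  n_e <- length(edge_use_counts(mesh))
  nrow(mesh$vertices) - n_e + nrow(mesh$faces)
}

# sparse vertex adjacency (symmetric 0/1) and degrees
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  a@x[] <- 1  # collapse duplicate triplets to unit weights
  methods::as(a, "CsparseMatrix")
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

face_areas <- function(mesh) {
  n <- face_normals(mesh, normalize = FALSE)
  sqrt(rowSums(n^2)) / 2
}

#' Remove unreferenced vertices
#' @param mesh a [surface_mesh].
#' @return a [surface_mesh] whose vertices are all referenced by faces.
#' @export
drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[mesh$faces], ncol = 3), validate = FALSE)
}

#' Keep only the largest connected component of a mesh
#' @param mesh a [surface_mesh].
#' @param warn emit a warning when components are dropped.
#' @return a [surface_mesh].
#' @export
largest_component <- function(mesh, warn = TRUE) {
  lab <- cpp_vertex_components(mesh$faces - 1L, nrow(mesh$vertices))
  tab <- tabulate(lab)
  keep <- which.max(tab)
  if (sum(tab > 0) > 1L) {
    if (warn) warning("mesh has ", sum(tab > 0),
                      " components; keeping the largest")
    fkeep <- lab[mesh$faces[, 1]] == keep
    mesh <- drop_unreferenced(
      surface_mesh(mesh$vertices, mesh$faces[fkeep, , drop = FALSE],
                   validate = FALSE))
  }
  mesh
}

#' Make face windings consistent
#'
#' Propagates a consistent winding across shared edges (each interior edge
#' traversed once per direction). Needed after isosurface extraction.
#' @param mesh a [surface_mesh].
#' @return a consistently wound [surface_mesh].
#' @export
orient_consistent <- function(mesh) {
  mesh$faces <- cpp_orient_consistent(mesh$faces - 1L) + 1L
  mesh
}

#' Orient a closed mesh outward
#'
#' Flips the face winding of a consistently oriented closed mesh so that its
#' signed volume is positive (outward normals).
#' @param mesh a closed, consistently oriented [surface_mesh].
#' @return a [surface_mesh].
#' @export
orient_outward <- function(mesh) {
  if (signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Closest points on a mesh surface
#'
#' For each query point, the closest point on any triangle of the mesh
#' (surface points, not only vertices).
#' @param mesh a [surface_mesh].
#' @param points numeric matrix `q x 3`.
#' @return list with `points` (`q x 3` closest surface points), `dist`
#'   (Euclidean distances, mm) and `face` (1-based face index).
#' @export
mesh_closest_points <- function(mesh, points) {
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_mesh_closest(mesh$vertices, mesh$faces - 1L, points)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh: ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", sep = "")
  if (nrow(x$faces) > 0L) {
    cat(if (is_closed_mesh(x)) ", closed" else
      paste0(", open (", boundary_edge_count(x), " boundary edges)"))
  }
  cat("\n")
  invisible(x)
}
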