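# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Geometry and acquisition parameters for synthetic chamber phantoms. The
#' slicing defaults emulate an axial cine stack: 8 mm slice spacing and
#' in-plane jitter of 0.5 mm (about a fifth of a 2.8 mm in-plane voxel).
#'
#' @param shape `"sphere"`, `"ellipsoid"` or `"blended_atrium"`.
#' @param size mm; radius for a sphere, 3 semi-axes for an ellipsoid or the
#'   body of the blended atrium.
#' @param slice_spacing mm between axial slices.
#' @param in_plane_noise_sd mm, Gaussian jitter of contour points.
#' @param seed integer seed for any randomised step.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid", "blended_atrium"),
                         size = NULL, slice_spacing = 8,
                         in_plane_noise_sd = 0.5, seed = 1L) {
  shape <- match.arg(shape)
  if (is.null(size))
    size <- switch(shape, sphere = 30, ellipsoid = c(30, 25, 20),
                   blended_atrium = c(32, 28, 24))
  if (any(size <= 0) || slice_spacing <= 0)
    stop("phantom_spec: sizes and spacing must be > 0")
  structure(list(shape = shape, size = size, slice_spacing = slice_spacing,
                 in_plane_noise_sd = in_plane_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Point-cloud specification
#'
#' Emulates an intra-chamber ultrasound acquisition: area-weighted surface
#' samples with Gaussian noise along the normal, a fraction of points
#' displaced outward by `epi_offset` (the epicardial reflection layer,
#' default 1.9 mm), and a fraction of far outliers.
#'
#' @param n_points number of samples.
#' @param surface_noise_sd mm.
#' @param epi_offset outward displacement of the epicardial layer, mm.
#' @param epi_fraction fraction of points in the epicardial layer, in
#'   `[0, 1]`.
#' @param outlier_fraction fraction of far outliers, in `[0, 1]`.
#' @param outlier_scale mm; outliers are scattered at this distance from
#'   the cloud centre.
#' @param seed integer seed.
#' @return object of class `cloud_spec`.
#' @export
cloud_spec <- function(n_points = 5000L, surface_noise_sd = 0.5,
                       epi_offset = 1.9, epi_fraction = 0,
                       outlier_fraction = 0, outlier_scale = 150,
                       seed = 1L) {
  if (epi_fraction < 0 || epi_fraction > 1 ||
      outlier_fraction < 0 || outlier_fraction > 1)
    stop("cloud_spec: fractions must be in [0, 1]")
  structure(list(n_points = as.integer(n_points),
                 surface_noise_sd = surface_noise_sd,
                 epi_offset = epi_offset, epi_fraction = epi_fraction,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale, seed = as.integer(seed)),
            class = "cloud_spec")
}

# unit icosphere: subdivided icosahedron with vertices projected to radius 1
icosphere <- function(subdivisions = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- surface_mesh(v, f)
  for (k in seq_len(subdivisions)) {
    m <- subdivide_midpoint(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  orient_outward(m)
}

#' Generate a synthetic chamber phantom mesh
#'
#' `sphere` and `ellipsoid` are subdivided icosahedra (vertices exactly on
#' the analytic surface); `blended_atrium` is an implicit smooth union of
#' an ellipsoid body, four tapered tube stubs emulating pulmonary veins and
#' one lateral pouch emulating the appendage, meshed by marching
#' tetrahedra. All outputs are closed genus-0 meshes, deterministic for a
#' given spec.
#'
#' @param spec a [phantom_spec].
#' @param subdivisions icosphere refinement level (sphere/ellipsoid).
#' @return a closed [surface_mesh].
#' @export
make_phantom <- function(spec = phantom_spec(), subdivisions = 4L) {
  switch(spec$shape,
    sphere = {
      m <- icosphere(subdivisions)
      m$vertices <- m$vertices * spec$size[1]
      m
    },
    ellipsoid = {
      m <- icosphere(subdivisions)
      m$vertices <- sweep(m$vertices, 2, rep(spec$size, length.out = 3), `*`)
      orient_outward(m)
    },
    blended_atrium = blended_atrium_mesh(rep(spec$size, length.out = 3)))
}

# smooth-min blend of implicit distance-like fields
smin <- function(a, b, k = 6) -log(exp(-a / k) + exp(-b / k)) * k

blended_atrium_mesh <- function(axes, n = 64L) {
  # implicit field: ellipsoid body + 4 pulmonary-vein stubs + appendage pouch
  stub <- function(p, base, dir, len, r0, r1) {
    # tapered capsule: distance to the clamped axis point minus the local
    # radius (r0 at the base, r1 at the tip)
    dir <- dir / sqrt(sum(dir^2))
    rel <- sweep(p, 2, base)
    tt <- as.vector(pmin(pmax(rel %*% dir, 0), len))
    rad <- sqrt(rowSums((rel - outer(tt, dir))^2))
    rad - (r0 + (r1 - r0) * tt / len)
  }
  field <- function(p) {
    f <- sqrt(rowSums(sweep(p, 2, axes, `/`)^2)) - 1
    f <- f * min(axes)                      # approximate mm units
    pv_dirs <- rbind(c(0.8, 0.5, 0.6), c(-0.8, 0.5, 0.6),
                     c(0.8, -0.5, 0.7), c(-0.8, -0.5, 0.7))
    # short ostial stubs (the veins themselves are excluded structures in
    # the pipeline, only their ostia shape the chamber silhouette)
    for (i in 1:4) {
      d <- pv_dirs[i, ] / sqrt(sum(pv_dirs[i, ]^2))
      base <- d * axes * 0.75
      f <- smin(f, stub(p, base, d, 0.4 * min(axes), 7, 4), k = 4)
    }
    f <- smin(f, stub(p, c(axes[1] * 0.7, 0, axes[3] * 0.2),
                      c(1, 0.15, 0.35), 0.35 * min(axes), 8, 5), k = 5)
    f
  }
  side <- 2 * max(axes) * 1.6
  origin <- rep(-side / 2, 3)
  h <- side / (n - 1)
  gx <- origin[1] + (0:(n - 1)) * h
  p <- as.matrix(expand.grid(x = gx, y = gx, z = gx))
  vals <- field(p)
  surf <- cpp_marching_tets(vals, n, n, n, origin, h, 0)
  m <- surface_mesh(surf$vertices, surf$faces + 1L, validate = FALSE)
  orient_outward(orient_consistent(largest_component(m, warn = FALSE)))
}

#' Adjacent-structure phantom: a cylindrical tube
#'
#' Closed tube mesh (capped cylinder) used as a stand-in for adjacent
#' thoracic structures such as the aorta or spine.
#'
#' @param p0,p1 end points of the axis, mm.
#' @param radius mm.
#' @param n_ring vertices per ring.
#' @param n_seg segments along the axis.
#' @return a closed [surface_mesh].
#' @export
make_tube <- function(p0, p1, radius, n_ring = 24L, n_seg = 12L) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  ax <- p1 - p0
  len <- sqrt(sum(ax^2))
  ax <- ax / len
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * ax) * ax
  u <- u / sqrt(sum(u^2))
  w <- c(ax[2] * u[3] - ax[3] * u[2], ax[3] * u[1] - ax[1] * u[3],
         ax[1] * u[2] - ax[2] * u[1])
  th <- 2 * pi * (0:(n_ring - 1)) / n_ring
  ring <- outer(cos(th), u) + outer(sin(th), w)
  verts <- do.call(rbind, lapply(0:n_seg, function(s)
    sweep(ring * radius, 2, p0 + ax * len * s / n_seg, `+`)))
  faces <- list()
  for (s in seq_len(n_seg)) {
    a <- (s - 1L) * n_ring + seq_len(n_ring)
    b <- s * n_ring + seq_len(n_ring)
    an <- a[c(2:n_ring, 1L)]
    bn <- b[c(2:n_ring, 1L)]
    faces[[s]] <- rbind(cbind(a, an, b), cbind(b, an, bn))
  }
  i0 <- nrow(verts) + 1L
  i1 <- nrow(verts) + 2L
  verts <- rbind(verts, p0, p1)
  r1 <- seq_len(n_ring)
  rJ <- n_seg * n_ring + seq_len(n_ring)
  faces[[n_seg + 1L]] <- cbind(i0, r1[c(2:n_ring, 1L)], r1)
  faces[[n_seg + 2L]] <- cbind(i1, rJ, rJ[c(2:n_ring, 1L)])
  f <- do.call(rbind, faces)
  dimnames(f) <- NULL
  orient_outward(surface_mesh(verts, f))
}

#' Slice a closed mesh into an axial contour stack
#'
#' Intersects the mesh with planes `z = z_min + k * spacing`, keeps the
#' largest intersection loop per plane, adds Gaussian in-plane jitter of sd
#' `spec$in_plane_noise_sd`, and also emits one mid-height transverse
#' contour (plane through the stack axis) stored in the returned set.
#'
#' @param mesh a closed [surface_mesh].
#' @param spec a [phantom_spec] (spacing, noise, seed).
#' @return a [contour_set] with the transverse contour attached.
#' @export
slice_to_contours <- function(mesh, spec = phantom_spec()) {
  if (!is_closed_mesh(mesh)) stop("slice_to_contours: mesh must be closed")
  v <- mesh$vertices
  zr <- range(v[, 3])
  # centre the slice grid on the object: the scanner grid is positioned
  # relative to the patient, not the chamber, and a grid whose first plane
  # is tangent to the chamber yields a degenerate empty slice
  rem <- (zr[2] - zr[1]) %% spec$slice_spacing
  off <- if (rem > 1e-9) rem / 2 else spec$slice_spacing / 2
  levels <- seq(zr[1] + off, zr[2] - 1e-6, by = spec$slice_spacing)
  contours <- list()
  with_seed(spec$seed, {
    for (z in levels) {
      loop <- largest_plane_loop(mesh, dim = 3L, level = z)
      if (is.null(loop) || nrow(loop) < 3L) next
      pts2 <- loop[, 1:2, drop = FALSE]
      if (spec$in_plane_noise_sd > 0)
        pts2 <- pts2 + matrix(stats::rnorm(length(pts2), 0,
                                           spec$in_plane_noise_sd),
                              ncol = 2)
      pose <- slice_pose(c(0, 0, z), c(1, 0, 0), c(0, 1, 0), "axial")
      contours[[length(contours) + 1L]] <- contour(pts2, pose)
    }
    if (length(contours) < 2L)
      stop("slice_to_contours: fewer than 2 non-empty slices")
    y0 <- mean(range(v[, 2]))
    tl <- largest_plane_loop(mesh, dim = 2L, level = y0)
    transverse <- NULL
    if (!is.null(tl) && nrow(tl) >= 3L) {
      pts2 <- tl[, c(1, 3), drop = FALSE]   # (x, z) in-plane coordinates
      if (spec$in_plane_noise_sd > 0)
        pts2 <- pts2 + matrix(stats::rnorm(length(pts2), 0,
                                           spec$in_plane_noise_sd),
                              ncol = 2)
      pose <- slice_pose(c(0, y0, 0), c(1, 0, 0), c(0, 0, 1), "transverse")
      transverse <- contour(pts2, pose)
    }
    contour_set(contours, transverse = transverse)
  })
}

# largest closed intersection loop of the mesh with plane x[dim] == level;
# returns ordered 3D points or NULL
largest_plane_loop <- function(mesh, dim, level) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- v[, dim] - level
  if (any(s == 0)) { level <- level + 1e-9; s <- v[, dim] - level }
  side <- s > 0
  cross_f <- which((side[f[, 1]] + side[f[, 2]] + side[f[, 3]]) %in% c(1L, 2L))
  if (length(cross_f) == 0L) return(NULL)
  # for each crossing face, the two crossed edges (keyed for welding)
  seg_from <- character(0); seg_to <- character(0)
  pt_map <- new.env(parent = emptyenv())
  edge_point <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    if (is.null(pt_map[[key]])) {
      t0 <- s[i] / (s[i] - s[j])
      pt_map[[key]] <- v[i, ] + t0 * (v[j, ] - v[i, ])
    }
    key
  }
  segs <- vector("list", length(cross_f))
  for (kk in seq_along(cross_f)) {
    tri <- f[cross_f[kk], ]
    e <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    crossed <- which(side[e[, 1]] != side[e[, 2]])
    if (length(crossed) != 2L) next
    k1 <- edge_point(e[crossed[1], 1], e[crossed[1], 2])
    k2 <- edge_point(e[crossed[2], 1], e[crossed[2], 2])
    segs[[kk]] <- c(k1, k2)
  }
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (length(segs) == 0L) return(NULL)
  # chain segments into loops (each key has exactly 2 partners on a closed
  # manifold mesh)
  adj <- new.env(parent = emptyenv())
  for (sg in segs) {
    adj[[sg[1]]] <- c(adj[[sg[1]]], sg[2])
    adj[[sg[2]]] <- c(adj[[sg[2]]], sg[1])
  }
  visited <- new.env(parent = emptyenv())
  best <- NULL; best_len <- -1
  for (start in ls(adj)) {
    if (!is.null(visited[[start]])) next
    loop <- character(0)
    cur <- start; prev <- ""
    repeat {
      visited[[cur]] <- TRUE
      loop <- c(loop, cur)
      nbrs <- adj[[cur]]
      nxt <- setdiff(nbrs, prev)[1]
      if (is.na(nxt) || is.null(nxt)) break
      prev <- cur; cur <- nxt
      if (cur == start) break
    }
    if (length(loop) >= 3L) {
      pts <- t(vapply(loop, function(k) pt_map[[k]], numeric(3)))
      # drop consecutive near-duplicates (crossings at shared mesh vertices)
      gap <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2))
      pts <- pts[gap > 1e-7, , drop = FALSE]
      if (nrow(pts) < 3L) next
      per <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
      if (per > best_len) { best_len <- per; best <- pts }
    }
  }
  best
}

#' Sample an intra-chamber-ultrasound style point cloud from a mesh
#'
#' Area-weighted surface sampling with Gaussian noise along the sampled
#' face normal; a fraction of points is displaced outward by
#' `spec$epi_offset` (epicardial reflections); a fraction is replaced by far
#' outliers scattered at `spec$outlier_scale` from the cloud centre.
#' Deterministic for a given seed.
#'
#' @param mesh a [surface_mesh] with outward orientation.
#' @param spec a [cloud_spec].
#' @return `n_points x 3` matrix, mm; the epicardial/outlier flags are
#'   attached as attributes `"layer"` (`"endo"`/`"epi"`/`"outlier"`).
#' @export
sample_cloud <- function(mesh, spec = cloud_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_points
    fa <- face_areas(mesh)
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = fa)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
    nrm <- face_normals(mesh)[fi, , drop = FALSE]
    layer <- rep("endo", n)
    n_epi <- round(spec$epi_fraction * n)
    if (n_epi > 0) {
      epi <- sample.int(n, n_epi)
      pts[epi, ] <- pts[epi, ] + spec$epi_offset * nrm[epi, , drop = FALSE]
      layer[epi] <- "epi"
    }
    if (spec$surface_noise_sd > 0)
      pts <- pts + stats::rnorm(n, 0, spec$surface_noise_sd) * nrm
    n_out <- round(spec$outlier_fraction * n)
    if (n_out > 0) {
      oi <- sample.int(n, n_out)
      dir <- matrix(stats::rnorm(3 * n_out), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      cen <- colMeans(mesh$vertices)
      pts[oi, ] <- sweep(dir * spec$outlier_scale, 2, cen, `+`)
      layer[oi] <- "outlier"
    }
    attr(pts, "layer") <- layer
    pts
  })
}

#' Synthetic per-vertex conduction fields with known contact structure
#'
#' Conduction-velocity fields are smooth low-order angular patterns scaled
#' into `[0.2, 1.5]` m/s. Pathological-conduction-pattern frequencies are
#' Poisson event counts over `duration_s` divided by the duration, with the
#' event rate multiplied by `effect` at vertices within 3 mm of the given
#' structure (base rates: focal firing 0.05, rotational activity 0.15,
#' irregular activity 0.65 events/s). Deterministic for a given seed.
#'
#' @param mesh the chamber [surface_mesh].
#' @param structure adjacent-structure [surface_mesh] (e.g. [make_tube]).
#' @param effect contact rate multiplier, `>= 1`.
#' @param duration_s recording duration, s.
#' @param seed integer seed.
#' @param contact_threshold mm (default 3).
#' @return list of [vertex_field]s (`cv_af`, `cv_long_cl`, `cv_short_cl`,
#'   `ff`, `lra`, `lia`) plus the `proximity_result` used (element
#'   `proximity`).
#' @export
make_fields <- function(mesh, structure, effect = 3, duration_s = 60,
                        seed = 1L, contact_threshold = 3) {
  if (effect < 1) stop("make_fields: effect must be >= 1")
  pr <- contact_mask(structure_distance(mesh, structure), contact_threshold)
  nv <- nrow(mesh$vertices)
  u <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
  u <- u / sqrt(rowSums(u^2))
  base_rates <- c(ff = 0.05, lra = 0.15, lia = 0.65)
  with_seed(seed, {
    smooth_cv <- function() {
      co <- stats::rnorm(9)
      f <- co[1] + co[2] * u[, 1] + co[3] * u[, 2] + co[4] * u[, 3] +
        co[5] * (u[, 1]^2 - u[, 2]^2) + co[6] * u[, 1] * u[, 2] +
        co[7] * u[, 2] * u[, 3] + co[8] * u[, 1] * u[, 3] +
        co[9] * (3 * u[, 3]^2 - 1)
      0.2 + 1.3 * (f - min(f)) / (max(f) - min(f))
    }
    out <- list(cv_af = vertex_field(smooth_cv(), "cv_af"),
                cv_long_cl = vertex_field(smooth_cv(), "cv_long_cl"),
                cv_short_cl = vertex_field(smooth_cv(), "cv_short_cl"))
    for (k in names(base_rates)) {
      rate <- rep(base_rates[[k]], nv)
      rate[pr$contact] <- rate[pr$contact] * effect
      counts <- stats::rpois(nv, rate * duration_s)
      out[[k]] <- vertex_field(counts / duration_s, k)
    }
    out$proximity <- pr
    out
  })
}
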