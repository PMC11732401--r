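#' Spherical exclusion region
#'
#' Reproducible proxy for the interactively marked regions removed before
#' registration (mitral valve, pulmonary veins, left atrial appendage).
#'
#' @param center 3-vector, mm.
#' @param radius mm, `> 0`.
#' @param label one of `"mitral_valve"`, `"pulmonary_vein"`, `"laa"`,
#'   `"other"`.
#' @return object of class `exclusion_region`.
#' @export
exclusion_region <- function(center, radius,
                             label = c("other", "mitral_valve",
                                       "pulmonary_vein", "laa")) {
  label <- match.arg(label)
  if (radius <= 0) stop("exclusion_region: radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius, label = label),
            class = "exclusion_region")
}

#' Read exclusion regions from a JSON sidecar
#'
#' Schema: `[{"label": "mitral_valve", "center_mm": [x,y,z],
#' "radius_mm": r}, ...]`.
#' @param path JSON file path.
#' @return list of [exclusion_region]s.
#' @export
read_exclusion_regions <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(d)
    exclusion_region(unlist(d$center_mm), d$radius_mm,
                     label = if (is.null(d$label)) "other" else d$label))
}

#' Remove mesh regions inside exclusion spheres
#'
#' Removes every face having any vertex inside any region sphere and drops
#' unreferenced vertices. With `cap_holes`, each resulting boundary loop is
#' closed with a fan to its centroid so the output is watertight. If the
#' removal disconnects the mesh, the largest component is kept with a
#' warning.
#'
#' @param mesh a [surface_mesh].
#' @param regions list of [exclusion_region]s (non-empty).
#' @param cap_holes close boundary loops with centroid fans.
#' @return the edited [surface_mesh].
#' @export
exclude_regions <- function(mesh, regions, cap_holes = FALSE) {
  if (inherits(regions, "exclusion_region")) regions <- list(regions)
  if (length(regions) == 0L) stop("exclude_regions: regions must be non-empty")
  v <- mesh$vertices
  inside <- rep(FALSE, nrow(v))
  for (r in regions) {
    d2 <- rowSums(sweep(v, 2, r$center)^2)
    inside <- inside | d2 < r$radius^2
  }
  bad_face <- inside[mesh$faces[, 1]] | inside[mesh$faces[, 2]] |
    inside[mesh$faces[, 3]]
  if (!any(bad_face)) return(mesh)
  if (all(bad_face)) stop("exclude_regions: all faces removed")
  out <- surface_mesh(v, mesh$faces[!bad_face, , drop = FALSE],
                      validate = FALSE)
  out <- largest_component(drop_unreferenced(out))
  if (cap_holes) out <- cap_boundary_loops(out)
  out
}

# close every boundary loop with a centroid fan
cap_boundary_loops <- function(mesh) {
  repeat {
    loops <- boundary_loops(mesh)
    if (length(loops) == 0L) break
    for (loop in loops) {
      cen <- colMeans(mesh$vertices[loop, , drop = FALSE])
      ci <- nrow(mesh$vertices) + 1L
      mesh$vertices <- rbind(mesh$vertices, cen)
      nl <- length(loop)
      # boundary loop comes oriented along the boundary direction; the fan
      # must run opposite to the existing boundary edges
      fan <- cbind(ci, loop[c(2:nl, 1L)], loop)
      mesh$faces <- rbind(mesh$faces, fan)
    }
    mesh <- surface_mesh(mesh$vertices, mesh$faces, validate = FALSE)
  }
  mesh
}

# boundary loops as ordered vertex index cycles (directed boundary edges)
boundary_loops <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(list())
  be <- e[key %in% bkey, , drop = FALSE]
  nxt <- stats::setNames(be[, 2], be[, 1])
  loops <- list()
  visited <- character()
  for (s in names(nxt)) {
    if (s %in% visited) next
    loop <- integer()
    cur <- s
    repeat {
      visited <- c(visited, cur)
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (is.na(cur) || !cur %in% names(nxt) || cur == s) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Directed / symmetric surface distance between meshes
#'
#' `a_to_b`: for each vertex of `a`, distance to the nearest point on the
#' triangles of `b` (surface points, not only vertices). `symmetric`: mean
#' of the two directed means, with the pooled per-point list.
#'
#' @param a,b [surface_mesh]es registered in the same frame.
#' @param direction `"symmetric"` (default), `"a_to_b"` or `"b_to_a"`.
#' @return object of class `distance_report`: list with `per_point` (mm),
#'   `mean`, `sd`, `direction`, and for symmetric reports the two directed
#'   means `mean_a_to_b`, `mean_b_to_a`.
#' @export
surface_distance <- function(a, b,
                             direction = c("symmetric", "a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  if (nrow(a$faces) == 0L || nrow(b$faces) == 0L)
    stop("surface_distance: empty mesh")
  d_ab <- function() mesh_closest_points(b, a$vertices)$dist
  d_ba <- function() mesh_closest_points(a, b$vertices)$dist
  rep_ <- switch(direction,
    a_to_b = { d <- d_ab(); list(per_point = d, mean = mean(d)) },
    b_to_a = { d <- d_ba(); list(per_point = d, mean = mean(d)) },
    symmetric = {
      d1 <- d_ab(); d2 <- d_ba()
      list(per_point = c(d1, d2), mean = (mean(d1) + mean(d2)) / 2,
           mean_a_to_b = mean(d1), mean_b_to_a = mean(d2))
    })
  rep_$sd <- stats::sd(rep_$per_point)
  rep_$direction <- direction
  class(rep_) <- "distance_report"
  rep_
}

#' @export
print.distance_report <- function(x, ...) {
  cat("surface distance (", x$direction, "): ", format(x$mean, digits = 3),
      " +/- ", format(x$sd, digits = 3), " mm over ", length(x$per_point),
      " points\n", sep = "")
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem volume `|sum_f (v0 . (v1 x v2)) / 6|`, reported in ml
#' (1 ml = 1000 mm^3). The mesh is auto-oriented outward by the sign of the
#' signed volume.
#'
#' @param mesh a closed, consistently oriented [surface_mesh].
#' @return volume in ml.
#' @export
enclosed_volume <- function(mesh) {
  if (!is_closed_mesh(mesh))
    stop("enclosed_volume: mesh is open (", boundary_edge_count(mesh),
         " boundary edges); use exclude_regions(cap_holes = TRUE) or cap first")
  abs(signed_volume(mesh)) / 1000
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh].
#' @return area in mm^2.
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Barycentric per-vertex area weights
#'
#' Each vertex receives one third of every incident triangle's area; the
#' weights sum to the total surface area.
#'
#' @param mesh a [surface_mesh].
#' @return numeric vector of per-vertex areas, mm^2.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh) / 3
  w <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- tapply(fa, mesh$faces[, k], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + as.numeric(acc)
  }
  w
}

#' Equivalent wall thickness from two nested reconstructions
#'
#' `(v_outer - v_inner) * 1000 / area_inner`: the volume difference between
#' an outer and an inner reconstruction spread uniformly over the inner
#' surface.
#'
#' @param v_outer,v_inner volumes, ml.
#' @param area_inner inner surface area, mm^2.
#' @return thickness in mm (negative with a warning when
#'   `v_outer < v_inner`).
#' @export
equivalent_wall_thickness <- function(v_outer, v_inner, area_inner) {
  if (area_inner <= 0) stop("equivalent_wall_thickness: area_inner must be > 0")
  th <- (v_outer - v_inner) * 1000 / area_inner
  if (th < 0) warning("equivalent_wall_thickness: negative thickness ",
                      "(v_outer < v_inner)")
  th
}

#' Geometric + clinical comparison of two registered reconstructions
#'
#' Emits the comparison metrics used for modality agreement: directed and
#' symmetric surface distance, enclosed volumes, and the relative volume of
#' `a` versus `b` in percent.
#'
#' @param a,b closed [surface_mesh]es in a common frame (e.g. MRI and ICUS
#'   reconstructions after registration).
#' @param regions optional list of [exclusion_region]s; when supplied,
#'   volumes are reported both before and after exclusion (with capping).
#' @return list with `distance` (symmetric [surface_distance] report),
#'   `volume_a_ml`, `volume_b_ml`, `relative_volume_pct`, and optionally
#'   `volume_a_excluded_ml`, `volume_b_excluded_ml`.
#' @export
compare_reconstructions <- function(a, b, regions = NULL) {
  out <- list(distance = surface_distance(a, b, "symmetric"),
              volume_a_ml = enclosed_volume(a),
              volume_b_ml = enclosed_volume(b))
  out$relative_volume_pct <- 100 * out$volume_a_ml / out$volume_b_ml
  if (!is.null(regions) && length(regions) > 0L) {
    out$volume_a_excluded_ml <-
      enclosed_volume(exclude_regions(a, regions, cap_holes = TRUE))
    out$volume_b_excluded_ml <-
      enclosed_volume(exclude_regions(b, regions, cap_holes = TRUE))
  }
  out
}
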