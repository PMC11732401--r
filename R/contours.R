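#' Slice pose
#'
#' Pose of a 2D imaging plane in the global patient frame: an origin (mm) and
#' two orthonormal in-plane axes. In-plane coordinates `(u, v)` map to the
#' global point `origin + u * axis_u + v * axis_v`.
#'
#' @param origin 3-vector, mm.
#' @param axis_u,axis_v orthonormal 3-vectors spanning the plane.
#' @param plane_label `"axial"` or `"transverse"`.
#' @return object of class `slice_pose`.
#' @export
slice_pose <- function(origin, axis_u, axis_v,
                       plane_label = c("axial", "transverse")) {
  plane_label <- match.arg(plane_label)
  origin <- as.numeric(origin); axis_u <- as.numeric(axis_u)
  axis_v <- as.numeric(axis_v)
  if (length(origin) != 3L || length(axis_u) != 3L || length(axis_v) != 3L)
    stop("slice_pose: origin/axis_u/axis_v must be 3-vectors")
  if (abs(sum(axis_u^2) - 1) > 1e-9 || abs(sum(axis_v^2) - 1) > 1e-9)
    stop("slice_pose: axis_u and axis_v must be unit vectors")
  if (abs(sum(axis_u * axis_v)) > 1e-9)
    stop("slice_pose: axis_u and axis_v must be orthogonal")
  structure(list(origin = origin, axis_u = axis_u, axis_v = axis_v,
                 plane_label = plane_label), class = "slice_pose")
}

plane_normal <- function(pose) {
  u <- pose$axis_u; v <- pose$axis_v
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Planar closed contour
#'
#' A closed polyline of in-plane 2D points (mm) together with its
#' [slice_pose]. Contours are always closed; the last point connects back to
#' the first.
#'
#' @param points2d `n x 2` matrix of in-plane coordinates, mm, `n >= 3`.
#' @param pose a [slice_pose].
#' @param check_simple verify the polygon is non-self-intersecting
#'   (O(n^2); skip for large resampled contours).
#' @return object of class `contour`.
#' @export
contour <- function(points2d, pose, check_simple = FALSE) {
  points2d <- matrix(as.numeric(as.matrix(points2d)), ncol = 2)
  if (nrow(points2d) < 3L) stop("contour: needs >= 3 points, got ",
                                nrow(points2d))
  nxt <- rbind(points2d[-1, , drop = FALSE], points2d[1, , drop = FALSE])
  seglen <- sqrt(rowSums((nxt - points2d)^2))
  if (any(seglen <= 1e-9))
    stop("contour: consecutive points closer than 1e-9 mm")
  if (check_simple && polygon_self_intersects(points2d))
    stop("contour: polygon is self-intersecting")
  structure(list(points2d = points2d, pose = pose, closed = TRUE),
            class = "contour")
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in seq.int(i + 2L, jmax)) {
      if (j > n) break
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Map a contour into global 3D coordinates
#'
#' Each in-plane point `(u, v)` maps to `origin + u * axis_u + v * axis_v`;
#' the per-slice map is an isometry.
#'
#' @param contour a [contour].
#' @return `n x 3` matrix of global points, mm, order preserved.
#' @export
to_global <- function(contour) {
  p <- contour$points2d
  pose <- contour$pose
  t(pose$origin + outer(pose$axis_u, p[, 1]) + outer(pose$axis_v, p[, 2]))
}

# out-of-plane (stack-axis) coordinate of a contour given a unit axis
stack_coordinate <- function(contour, axis) sum(contour$pose$origin * axis)

#' Sparse contour-stack representation of a chamber
#'
#' An ordered stack of axial [contour]s plus two lid points that close the
#' surface beyond the extreme slices. When lids are omitted they are placed
#' at the centroid of each extreme contour, offset outward along the stack
#' axis by one mean slice spacing: the chamber boundary lies somewhere in
#' the one-spacing gap beyond the last slice with signal, and the cone fan
#' closing the surface to the lid encloses less volume than the rounded cap
#' it stands in for, so the far end of that gap is the less biased apex.
#'
#' @param contours list of axial [contour]s (any order; sorted by their
#'   out-of-plane coordinate).
#' @param lid_low,lid_high optional 3-vectors, mm.
#' @param transverse optional transverse [contour] used for slice alignment.
#' @return object of class `contour_set`.
#' @export
contour_set <- function(contours, lid_low = NULL, lid_high = NULL,
                        transverse = NULL) {
  if (length(contours) < 2L)
    stop("contour_set: needs >= 2 contours, got ", length(contours))
  axis <- plane_normal(contours[[1]]$pose)
  axis <- axis / sqrt(sum(axis^2))
  z <- vapply(contours, stack_coordinate, 0, axis = axis)
  ord <- order(z)
  contours <- contours[ord]
  z <- z[ord]
  if (any(diff(z) <= 0))
    stop("contour_set: out-of-plane coordinates must be strictly monotone")
  spacing <- mean(diff(z))
  cent3 <- function(ct) colMeans(to_global(ct))
  if (is.null(lid_low))
    lid_low <- cent3(contours[[1]]) - axis * spacing
  if (is.null(lid_high))
    lid_high <- cent3(contours[[length(contours)]]) + axis * spacing
  lid_low <- as.numeric(lid_low); lid_high <- as.numeric(lid_high)
  if (sum(lid_low * axis) >= z[1])
    stop("contour_set: lid_low must lie beyond the lowest contour")
  if (sum(lid_high * axis) <= z[length(z)])
    stop("contour_set: lid_high must lie beyond the highest contour")
  structure(list(contours = contours, lid_low = lid_low, lid_high = lid_high,
                 stack_axis = axis, transverse = transverse),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  z <- vapply(x$contours, stack_coordinate, 0, axis = x$stack_axis)
  cat("contour_set: ", length(x$contours), " axial contours, stack range [",
      round(min(z), 2), ", ", round(max(z), 2), "] mm",
      if (!is.null(x$transverse)) ", 1 transverse contour", "\n", sep = "")
  invisible(x)
}

#' Resample a closed contour at equal arc length
#'
#' Places `K` points at equal arc-length spacing along the closed polyline,
#' starting at the original first vertex; the winding is normalised to
#' counter-clockwise about the slice normal `axis_u x axis_v`.
#'
#' @param contour a [contour].
#' @param K number of points, `>= 3`.
#' @return a resampled [contour] with `K` points.
#' @export
resample_contour <- function(contour, K) {
  if (K < 3L) stop("resample_contour: K must be >= 3")
  p <- contour$points2d
  # normalise winding to CCW (positive shoelace area), keep first vertex
  if (polygon_area2(p) < 0) {
    n <- nrow(p)
    p <- p[c(1L, n:2L), , drop = FALSE]
  }
  closed <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  s <- per * (seq_len(K) - 1L) / K
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  t0 <- (s - cum[idx]) / seg[idx]
  q <- closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * t0
  contour(q, contour$pose)
}

polygon_area2 <- function(p) {
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(p[, 1] * nxt[, 2] - nxt[, 1] * p[, 2]) / 2
}

contour_perimeter <- function(contour) {
  p <- contour$points2d
  closed <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

#' Align axial contours against a transverse contour
#'
#' Applies, to each axial contour whose plane the transverse contour
#' crosses, the in-plane rigid translation that minimises the summed
#' distance between the crossing points and the contour boundary. Slices not
#' crossed by the transverse contour are unchanged. Rotation is not
#' adjusted.
#'
#' @param cs a [contour_set].
#' @param transverse a transverse [contour]; defaults to the one stored in
#'   `cs`.
#' @return a [contour_set] with corrected contours; the applied in-plane
#'   corrections (mm) are attached as attribute `"corrections"`.
#' @export
align_axial_stack <- function(cs, transverse = cs$transverse) {
  if (is.null(transverse)) stop("align_axial_stack: no transverse contour")
  tg <- to_global(transverse)
  tg_closed <- rbind(tg, tg[1, ])
  any_cross <- FALSE
  corrections <- matrix(0, length(cs$contours), 2)
  for (j in seq_along(cs$contours)) {
    ct <- cs$contours[[j]]
    n <- plane_normal(ct$pose)
    d <- sum(ct$pose$origin * n)
    s <- tg_closed %*% n - d
    cross <- which(s[-length(s)] * s[-1] < 0)
    if (length(cross) == 0L) next
    any_cross <- TRUE
    t0 <- -s[cross] / (s[cross + 1L] - s[cross])
    x3 <- tg_closed[cross, , drop = FALSE] +
      (tg_closed[cross + 1L, , drop = FALSE] - tg_closed[cross, , drop = FALSE]) * as.vector(t0)
    # crossing points in the axial slice's in-plane coordinates
    rel <- sweep(x3, 2, ct$pose$origin)
    x2 <- cbind(rel %*% ct$pose$axis_u, rel %*% ct$pose$axis_v)
    poly <- ct$points2d
    obj <- function(tt) {
      sum(vapply(seq_len(nrow(x2)), function(i)
        point_polyline_distance2(x2[i, ] - tt, poly), 0))
    }
    # initial guess: mean offset from crossing points to their closest
    # boundary points
    cp <- t(vapply(seq_len(nrow(x2)), function(i)
      closest_on_polyline2(x2[i, ], poly), numeric(2)))
    init <- colMeans(x2 - cp)
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    tt <- fit$par
    corrections[j, ] <- tt
    cs$contours[[j]] <- contour(sweep(poly, 2, tt, `+`), ct$pose)
  }
  if (!any_cross) {
    warning("align_axial_stack: transverse contour does not cross any axial plane; returning input unchanged")
    attr(cs, "corrections") <- corrections
    return(cs)
  }
  attr(cs, "corrections") <- corrections
  cs
}

# distance from a 2D point to a closed polyline
point_polyline_distance2 <- function(x, poly) {
  sqrt(sum((x - closest_on_polyline2(x, poly))^2))
}

closest_on_polyline2 <- function(x, poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  ab <- b - a
  len2 <- rowSums(ab^2)
  tt <- ((x[1] - a[, 1]) * ab[, 1] + (x[2] - a[, 2]) * ab[, 2]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  px <- a + ab * tt
  d2 <- (px[, 1] - x[1])^2 + (px[, 2] - x[2])^2
  px[which.min(d2), ]
}

#' Read a contour set from JSON
#'
#' The schema is
#' `{"frame":"mm-global", "slices":[{"plane":"axial|transverse",
#' "origin":[x,y,z], "axis_u":[..], "axis_v":[..], "points":[[u,v],...]},...],
#' "lid_low":[x,y,z], "lid_high":[x,y,z]}`; lids are optional.
#'
#' @param path JSON file path.
#' @return a [contour_set] (a transverse slice, if present, is stored in the
#'   set's `transverse` element).
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed contour JSON in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$slices)) stop("contour JSON: missing field 'slices'")
  need_num <- function(x, field, n) {
    if (is.null(x)) stop("contour JSON: missing field '", field, "'")
    x <- suppressWarnings(as.numeric(unlist(x)))
    if (length(x) != n || anyNA(x))
      stop("contour JSON: field '", field, "' must be ", n, " numbers")
    x
  }
  axial <- list(); transverse <- NULL
  for (k in seq_along(doc$slices)) {
    sl <- doc$slices[[k]]
    plane <- sl$plane
    if (is.null(plane) || !plane %in% c("axial", "transverse"))
      stop("contour JSON: slices[", k, "].plane must be 'axial' or 'transverse'")
    origin <- need_num(sl$origin, paste0("slices[", k, "].origin"), 3)
    au <- need_num(sl$axis_u, paste0("slices[", k, "].axis_u"), 3)
    av <- need_num(sl$axis_v, paste0("slices[", k, "].axis_v"), 3)
    if (is.null(sl$points) || length(sl$points) < 3L)
      stop("contour JSON: slices[", k, "].points needs >= 3 points, got ",
           length(sl$points))
    pts <- t(vapply(sl$points, function(p)
      need_num(p, paste0("slices[", k, "].points[]"), 2), numeric(2)))
    ct <- contour(pts, slice_pose(origin, au, av, plane))
    if (plane == "axial") axial[[length(axial) + 1L]] <- ct
    else transverse <- ct
  }
  lid_low <- if (!is.null(doc$lid_low)) need_num(doc$lid_low, "lid_low", 3)
  lid_high <- if (!is.null(doc$lid_high)) need_num(doc$lid_high, "lid_high", 3)
  contour_set(axial, lid_low = lid_low, lid_high = lid_high,
              transverse = transverse)
}

#' Write a contour set to JSON
#' @param cs a [contour_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(cs, path) {
  slice_doc <- function(ct) list(
    plane = ct$pose$plane_label,
    origin = ct$pose$origin, axis_u = ct$pose$axis_u, axis_v = ct$pose$axis_v,
    points = ct$points2d)
  slices <- lapply(cs$contours, slice_doc)
  if (!is.null(cs$transverse))
    slices[[length(slices) + 1L]] <- slice_doc(cs$transverse)
  doc <- list(frame = "mm-global", slices = slices,
              lid_low = cs$lid_low, lid_high = cs$lid_high)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
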