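#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation 3-vector, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must be a 3-vector")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal (R'R = I)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle ",
    format(rotation_angle_deg(x$rotation), digits = 4), " deg, translation ",
    paste(format(x$translation, digits = 4), collapse = " "), " mm\n", sep = "")
  invisible(x)
}

rotation_angle_deg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

#' Apply a rigid transform to a mesh or points
#'
#' `v' = R v + t` per vertex; faces unchanged.
#' @param mesh a [surface_mesh] or an `n x 3` matrix of points.
#' @param T a [rigid_transform].
#' @return the transformed object.
#' @export
apply_transform <- function(mesh, T) {
  stopifnot(inherits(T, "rigid_transform"))
  if (inherits(mesh, "surface_mesh")) {
    mesh$vertices <- transform_points(mesh$vertices, T)
    mesh
  } else transform_points(as.matrix(mesh), T)
}

transform_points <- function(p, T) {
  sweep(p %*% t(T$rotation), 2, T$translation, `+`)
}

#' Compose rigid transforms
#'
#' `compose(T1, T2)` is the transform applying `T1` first, then `T2`:
#' `(T2 o T1)(x) = R2 (R1 x + t1) + t2`.
#' @param T1,T2 [rigid_transform]s.
#' @return a [rigid_transform].
#' @export
compose <- function(T1, T2) {
  rigid_transform(T2$rotation %*% T1$rotation,
                  as.vector(T2$rotation %*% T1$translation) + T2$translation)
}

#' Invert a rigid transform
#' @param T a [rigid_transform].
#' @return the inverse [rigid_transform].
#' @export
invert_transform <- function(T) {
  rigid_transform(t(T$rotation), -as.vector(t(T$rotation) %*% T$translation))
}

#' Generalized ICP configuration
#'
#' @param max_iterations iteration cap.
#' @param convergence_tol mm; stop when the RMS correspondence residual
#'   changes by less than this.
#' @param k_neighbors neighbourhood size for per-point covariance
#'   estimation.
#' @param covariance_epsilon replacement for the smallest covariance
#'   eigenvalue (plane-to-plane model).
#' @param max_correspondence_distance mm; pairs farther apart are ignored.
#' @return object of class `gicp_config`.
#' @export
gicp_config <- function(max_iterations = 100L, convergence_tol = 1e-5,
                        k_neighbors = 20L, covariance_epsilon = 1e-3,
                        max_correspondence_distance = 20) {
  cfg <- list(max_iterations = as.integer(max_iterations),
              convergence_tol = convergence_tol,
              k_neighbors = as.integer(k_neighbors),
              covariance_epsilon = covariance_epsilon,
              max_correspondence_distance = max_correspondence_distance)
  if (any(vapply(cfg, as.numeric, 0) <= 0)) stop("gicp_config: all parameters must be positive")
  structure(cfg, class = "gicp_config")
}

# plane-to-plane covariances: local PCA with eigenvalues regularised to
# (1, 1, eps); returned flattened row-major as an n x 9 matrix
gicp_covariances <- function(pts, k, eps) {
  nn <- cpp_knn(pts, pts, as.integer(min(k, nrow(pts))))$idx
  out <- matrix(0, nrow(pts), 9)
  for (i in seq_len(nrow(pts))) {
    ev <- eigen(stats::cov(pts[nn[i, ], , drop = FALSE]), symmetric = TRUE)
    u <- ev$vectors
    out[i, ] <- as.vector(t(u %*% diag(c(1, 1, eps)) %*% t(u)))
  }
  out
}

#' Generalized (plane-to-plane) ICP registration
#'
#' Rigidly registers the source mesh onto the target. Per-point covariances
#' are estimated from `k_neighbors`-point neighbourhoods with the smallest
#' eigenvalue replaced by `covariance_epsilon`, so residuals are weighted by
#' the combined Mahalanobis metric `(C_B + R C_A R')^{-1}` (plane-to-plane).
#' The transform is initialised by centroid alignment plus principal-axes
#' rotation, disambiguating axis signs by the lowest initial cost over the
#' four proper sign combinations. Each iteration recomputes nearest-neighbour
#' correspondences (capped at `max_correspondence_distance`) and takes a
#' damped Gauss-Newton step; steps that would increase the RMS
#' correspondence residual are halved, so the recorded cost sequence is
#' non-increasing.
#'
#' @param source,target [surface_mesh]es (their vertices are the point
#'   sets) or `n x 3` matrices.
#' @param cfg a [gicp_config].
#' @return object of class `gicp` with elements `transform` (source to
#'   target), `inverse`, `rms` (final RMS residual, mm), `cost_trace`,
#'   `iterations`, `converged`.
#' @export
generalized_icp <- function(source, target, cfg = gicp_config()) {
  src <- if (inherits(source, "surface_mesh")) source$vertices else as.matrix(source)
  tgt <- if (inherits(target, "surface_mesh")) target$vertices else as.matrix(target)
  if (nrow(src) == 0L || nrow(tgt) == 0L) stop("generalized_icp: empty input")
  ca <- gicp_covariances(src, cfg$k_neighbors, cfg$covariance_epsilon)
  cb <- gicp_covariances(tgt, cfg$k_neighbors, cfg$covariance_epsilon)

  rms_at <- function(T) {
    moved <- transform_points(src, T)
    d <- cpp_knn(tgt, moved, 1L)$dist[, 1]
    d <- d[d <= cfg$max_correspondence_distance]
    if (length(d) == 0L)
      stop("generalized_icp: no correspondences within max_correspondence_distance = ",
           cfg$max_correspondence_distance,
           " mm; consider a larger threshold")
    sqrt(mean(d^2))
  }

  refine <- function(T, cost) {
    trace <- cost
    converged <- FALSE
    iter <- 0L
    while (iter < cfg$max_iterations) {
      iter <- iter + 1L
      moved <- transform_points(src, T)
      nn <- cpp_knn(tgt, moved, 1L)
      keep <- which(nn$dist[, 1] <= cfg$max_correspondence_distance)
      if (length(keep) < 3L)
        stop("generalized_icp: no correspondences within max_correspondence_distance = ",
             cfg$max_correspondence_distance, " mm; consider a larger threshold")
      pj <- nn$idx[keep, 1]
      # Gauss-Newton on (omega, t): residual r_i = (R p_i + t) - q_i,
      # weighted by M_i = (C_B + R C_A R')^{-1}
      acc <- cpp_gicp_accumulate(moved, tgt, as.integer(keep),
                                 as.integer(pj), ca, cb, T$rotation)
      delta <- tryCatch(solve(acc$H, -acc$g), error = function(e) rep(0, 6))
      if (all(abs(delta) < 1e-14)) { converged <- TRUE; break }
      step <- 1
      improved <- FALSE
      for (h in 0:5) {
        Tc <- compose(T, delta_transform(step * delta))
        rc <- rms_at(Tc)
        if (rc <= cost + 1e-15) {
          T <- Tc
          improved <- TRUE
          delta_cost <- cost - rc
          cost <- rc
          break
        }
        step <- step / 2
      }
      trace <- c(trace, cost)
      if (!improved) { converged <- TRUE; break }
      if (delta_cost < cfg$convergence_tol) { converged <- TRUE; break }
    }
    list(T = T, rms = cost, trace = trace, iterations = iter,
         converged = converged)
  }

  # initialisation: centroids + principal axes; each of the 4 proper axis
  # sign combinations is refined to convergence and the lowest final cost
  # wins (the up-front sign choice is ambiguous for near-symmetric shapes)
  cs <- colMeans(src); ct <- colMeans(tgt)
  us <- svd(crossprod(sweep(src, 2, cs)) / nrow(src))$u
  ut <- svd(crossprod(sweep(tgt, 2, ct)) / nrow(tgt))$u
  if (det(us) < 0) us[, 3] <- -us[, 3]
  if (det(ut) < 0) ut[, 3] <- -ut[, 3]
  inits <- lapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                  function(signs) ut %*% diag(signs) %*% t(us))
  # also centroid-only: inputs already in one patient frame are near-aligned,
  # and PCA axes estimated from uneven vertex densities can start worse
  inits <- c(inits, list(diag(3)))
  best <- NULL
  for (R0 in inits) {
    T0 <- rigid_transform(R0, ct - as.vector(R0 %*% cs))
    run <- refine(T0, rms_at(T0))
    if (is.null(best) || run$rms < best$rms) best <- run
  }
  structure(list(transform = best$T, inverse = invert_transform(best$T),
                 rms = best$rms, cost_trace = best$trace,
                 iterations = best$iterations, converged = best$converged),
            class = "gicp")
}

# small rigid increment from (omega, t): rotation exp([omega]x)
delta_transform <- function(delta) {
  w <- delta[1:3]
  th <- sqrt(sum(w^2))
  if (th < 1e-30) R <- diag(3)
  else {
    k <- w / th
    Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  }
  rigid_transform(R, delta[4:6])
}

#' @export
print.gicp <- function(x, ...) {
  cat("generalized ICP: RMS residual ", format(x$rms, digits = 4), " mm after ",
      x$iterations, " iterations (",
      if (x$converged) "converged" else "iteration cap", ")\n", sep = "")
  print(x$transform)
  invisible(x)
}

#' Read/write rigid transforms as JSON
#'
#' JSON schema `{"rotation": [[..3x3..]], "translation_mm": [x,y,z]}`. A
#' plain-text 4x4 homogeneous matrix (whitespace-separated) is also
#' accepted on read and written with `format = "matrix"`.
#'
#' @param path file path.
#' @return a [rigid_transform].
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  if (startsWith(first, "{")) {
    doc <- jsonlite::fromJSON(path)
    rigid_transform(doc$rotation, doc$translation_mm)
  } else {
    m <- as.matrix(utils::read.table(path))
    if (!all(dim(m) == c(4L, 4L))) stop("transform matrix must be 4x4")
    rigid_transform(m[1:3, 1:3], m[1:3, 4])
  }
}

#' @rdname read_transform
#' @param T a [rigid_transform].
#' @param format `"json"` or `"matrix"` (plain-text homogeneous 4x4).
#' @export
write_transform <- function(T, path, format = c("json", "matrix")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(rotation = T$rotation,
                              translation_mm = T$translation),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    m <- rbind(cbind(T$rotation, T$translation), c(0, 0, 0, 1))
    utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
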