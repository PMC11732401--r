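#' Fit a 3D thin-plate-spline deformation
#'
#' Minimises `lambda * sum_i ||F(P_i) - Q_i'||^2 + J(F)` where `J` is the
#' second-order bending energy in three dimensions, whose kernel is
#' `phi(r) = r`. The fitted map is
#' `F(x) = a0 + A x + sum_i c_i * phi(||x - P_i||)` with the kernel
#' coefficients orthogonal to constants and linear functions (the TPS side
#' conditions). The regularised square system carries `1/lambda` on the
#' kernel diagonal, so `lambda -> Inf` approaches interpolation and
#' `lambda -> 0` approaches the affine least-squares fit.
#'
#' @param P `A x 3` control points, mm; `A >= 4`, non-coplanar.
#' @param Q_prime `A x 3` targets, mm.
#' @param lambda_ data-term weight, `> 0`.
#' @return object of class `tps_field` with elements `control_points`,
#'   `affine` (4 x 3, row 1 the offset), `coefficients` (A x 3), `lambda`.
#' @export
tps_fit <- function(P, Q_prime, lambda_) {
  P <- as.matrix(P); Q_prime <- as.matrix(Q_prime)
  if (ncol(P) != 3L || ncol(Q_prime) != 3L) stop("tps_fit: inputs must be n x 3")
  if (nrow(P) != nrow(Q_prime)) stop("tps_fit: P and Q_prime sizes differ")
  a <- nrow(P)
  if (a < 4L) stop("tps_fit: needs >= 4 control points")
  if (lambda_ <= 0) stop("tps_fit: lambda_ must be > 0")
  Phi <- cbind(1, P)
  if (qr(Phi)$rank < 4L)
    stop("tps_fit: control points are coplanar or otherwise rank-deficient; ",
         "the TPS system is singular")
  K <- as.matrix(stats::dist(P))          # phi(r) = r
  M <- rbind(cbind(K + diag(1 / lambda_, a), Phi),
             cbind(t(Phi), matrix(0, 4, 4)))
  rhs <- rbind(Q_prime, matrix(0, 4, 3))
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("tps_fit: singular TPS system (degenerate control points): ",
         conditionMessage(e)))
  structure(list(control_points = P,
                 coefficients = sol[seq_len(a), , drop = FALSE],
                 affine = sol[a + 1:4, , drop = FALSE],
                 lambda = lambda_),
            class = "tps_field")
}

#' Evaluate a thin-plate-spline field at points
#' @param object a [tps_fit] result.
#' @param newdata `n x 3` matrix of points, mm.
#' @param ... unused.
#' @return `n x 3` matrix `F(newdata)`.
#' @export
predict.tps_field <- function(object, newdata, ...) {
  x <- matrix(as.numeric(as.matrix(newdata)), ncol = 3)
  p <- object$control_points
  # pairwise distances x -> control points
  d <- sqrt(pmax(outer(rowSums(x^2), rowSums(p^2), `+`) - 2 * x %*% t(p), 0))
  cbind(1, x) %*% object$affine + d %*% object$coefficients
}

#' @export
print.tps_field <- function(x, ...) {
  cat("tps_field: ", nrow(x$control_points), " control points, lambda = ",
      format(x$lambda), ", bending energy ~ ",
      format(tps_bending_energy(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Bending energy of a fitted TPS (up to a constant factor)
#' @param field a `tps_field`.
#' @return non-negative scalar; 0 for a purely affine map.
#' @export
tps_bending_energy <- function(field) {
  K <- as.matrix(stats::dist(field$control_points))
  # for the biharmonic kernel the quadratic form is -c' K c on the side-
  # condition subspace (positive semi-definite there)
  e <- -sum(field$coefficients * (K %*% field$coefficients))
  max(e, 0)
}

#' Apply a TPS deformation to a mesh, guarding orientation
#'
#' Maps every vertex through the field, keeping faces fixed. To approximate
#' a diffeomorphic application, a step-halving guard rejects any update that
#' flips the orientation of a face (normal reversal) or collapses its area,
#' and retries with the displacement halved, up to 6 halvings; if the guard
#' still fails the mesh is returned unchanged with a warning.
#'
#' @param field a `tps_field`.
#' @param mesh a [surface_mesh].
#' @return the deformed [surface_mesh]; the accepted displacement fraction
#'   is attached as attribute `"step_scale"` (0 when rejected).
#' @export
apply_tps <- function(field, mesh) {
  v0 <- mesh$vertices
  v1 <- predict(field, v0)
  n0 <- face_normals(mesh)
  s <- 1
  for (h in 0:6) {
    cand <- mesh
    cand$vertices <- v0 + s * (v1 - v0)
    nn <- face_normals(cand, normalize = FALSE)
    area2 <- sqrt(rowSums(nn^2))
    ok <- all(area2 > 1e-12) &&
      all(rowSums(nn * n0) > 0)
    if (ok) {
      attr(cand, "step_scale") <- s
      return(cand)
    }
    s <- s / 2
  }
  warning("apply_tps: orientation guard failed after 6 halvings; step rejected")
  attr(mesh, "step_scale") <- 0
  mesh
}
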