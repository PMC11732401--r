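test_that("TPS reproduces rigid motions exactly with zero bending energy", {
  set.seed(3)
  P <- matrix(rnorm(60, sd = 20), ncol = 3)
  R <- rotation_axis(c(1, 2, 3), 25)
  tmove <- c(4, -7, 2)
  Q <- sweep(P %*% t(R), 2, tmove, `+`)
  f <- tps_fit(P, Q, 1e3)
  grid <- as.matrix(expand.grid(x = seq(-30, 30, length.out = 10),
                                y = seq(-30, 30, length.out = 10),
                                z = seq(-30, 30, length.out = 10)))
  expect_lt(max(abs(predict(f, grid) -
                      sweep(grid %*% t(R), 2, tmove, `+`))), 1e-8)
  expect_lt(max(abs(predict(f, P) - Q)), 1e-8)
  expect_lt(tps_bending_energy(f), 1e-8)
})

test_that("large lambda approaches interpolation of the targets", {
  set.seed(4)
  P <- matrix(rnorm(45, sd = 15), ncol = 3)
  Q <- P + matrix(rnorm(45), ncol = 3)
  f <- tps_fit(P, Q, 1e8)
  expect_lt(max(abs(predict(f, P) - Q)), 1e-4)
})

test_that("lambda -> 0 converges to the affine least-squares fit", {
  set.seed(5)
  P <- matrix(rnorm(90, sd = 15), ncol = 3)
  Q <- P %*% matrix(c(1.1, 0.1, 0, -0.05, 0.9, 0.02, 0, 0.1, 1), 3) +
    matrix(rnorm(90, sd = 2), ncol = 3)
  af <- qr.solve(cbind(1, P), Q)              # closed-form affine regression
  devs <- vapply(c(1e-3, 1e-4, 1e-5, 1e-6), function(l) {
    f <- tps_fit(P, Q, l)
    max(abs(f$affine - af))
  }, 0)
  expect_true(all(diff(devs) < 0))            # converges towards the affine fit
  expect_lt(devs[4], 1e-3)
  expect_lt(max(abs(tps_fit(P, Q, 1e-6)$coefficients)), 1e-5)
})

test_that("TPS residual at control points decreases as lambda grows", {
  set.seed(6)
  P <- matrix(rnorm(45, sd = 15), ncol = 3)
  Q <- P + matrix(rnorm(45), ncol = 3)
  res <- vapply(c(1e-2, 1, 1e2, 1e4, 1e6), function(l)
    sum((predict(tps_fit(P, Q, l), P) - Q)^2), 0)
  expect_true(all(diff(res) <= 1e-10))
})

test_that("TPS side conditions hold and degenerate control points error", {
  set.seed(7)
  P <- matrix(rnorm(45, sd = 15), ncol = 3)
  Q <- P + matrix(rnorm(45), ncol = 3)
  f <- tps_fit(P, Q, 10)
  orth <- crossprod(cbind(1, P), f$coefficients)
  expect_lt(max(abs(orth)), 1e-8)
  Pflat <- cbind(matrix(rnorm(30), ncol = 2), 0)   # coplanar
  expect_error(tps_fit(Pflat, Pflat, 10), "coplanar|rank")
  expect_error(tps_fit(P[1:3, ], Q[1:3, ], 10), ">= 4")
  expect_error(tps_fit(P, Q, 0), "lambda")
})

test_that("apply_tps maps vertices and guards face orientation", {
  m <- sphere_mesh(10, 2L)
  set.seed(8)
  P <- matrix(rnorm(45, sd = 12), ncol = 3)
  ident <- tps_fit(P, P, 1e3)
  expect_equal(apply_tps(ident, m)$vertices, m$vertices, tolerance = 1e-8)
  shift <- tps_fit(P, sweep(P, 2, c(3, 0, 0), `+`), 1e3)
  moved <- apply_tps(shift, m)
  expect_equal(moved$vertices, sweep(m$vertices, 2, c(3, 0, 0), `+`),
               tolerance = 1e-6)
  # a collapsing map (everything to one plane, then inverted) must trigger
  # the step-halving guard and never emit flipped faces
  huge <- tps_fit(P, cbind(-2 * P[, 1], P[, 2], P[, 3]), 1e6)
  out <- suppressWarnings(apply_tps(huge, m))
  n0 <- atriamesh:::face_normals(m)
  n1 <- atriamesh:::face_normals(out)
  expect_true(all(rowSums(n0 * n1) > 0))
})
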