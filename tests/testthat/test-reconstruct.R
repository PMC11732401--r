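test_that("contour-to-mesh distance matches analytic and brute-force values", {
  # mesh passing exactly through the contour points
  cs <- two_square_set()
  m <- build_tubular_mesh(cs, 4L)
  d <- contour_to_mesh_distance(m, cs, dense_K = 120L)
  expect_lt(d$mean, 1e-9)
  expect_lt(d$sd, 1e-9)

  # unit sphere mesh vs circle contour of radius 2 at z = 0
  unit <- sphere_mesh(1, 3L)
  circ2 <- contour_set(list(circle_contour(2, z = -0.2),
                            circle_contour(2, z = 0.2)))
  d2 <- contour_to_mesh_distance(unit, circ2, dense_K = 100L)
  expect_equal(d2$mean, sqrt(2^2 + 0.2^2) - 1, tolerance = 0.01)

  # oracle equivalence on random contour points
  m3 <- sphere_mesh(20, 2L)
  cs3 <- contour_set(list(circle_contour(22, z = -5), circle_contour(22, z = 5)))
  pts <- do.call(rbind, lapply(cs3$contours, function(ct)
    to_global(resample_contour(ct, 50L))))
  expect_equal(contour_to_mesh_distance(m3, cs3, dense_K = 50L)$distances,
               bf_mesh_distance(m3, pts), tolerance = 1e-10)
  expect_error(contour_to_mesh_distance(
    surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)), cs3), "empty")
})

test_that("max_outer_iters = 0 returns the initial tubular mesh", {
  cs <- sphere_contours()
  cfg <- reconstruction_config(max_outer_iters = 0L)
  fit <- reconstruct(cs, cfg)
  m0 <- build_tubular_mesh(cs, cfg$K)
  expect_equal(fit$mesh$vertices, m0$vertices, tolerance = 1e-12)
  expect_identical(fit$iterations, 0L)
})

test_that("sphere phantom round trip: sub-voxel distance, volume within 5%", {
  cs <- sphere_contours()
  fit <- suppressWarnings(reconstruct(cs))
  expect_lt(fit$distance$mean, 0.5)
  v <- enclosed_volume(fit$mesh)
  expect_lt(abs(v - 113.097) / 113.097, 0.05)
  expect_true(is_closed_mesh(fit$mesh))
  expect_true(is_oriented_mesh(fit$mesh))
  expect_gt(min(atriamesh:::face_areas(fit$mesh)), 1e-9)
  # accepted distance trace is non-increasing
  expect_true(all(diff(fit$trace) <= 1e-12))
  # residuals method exposes the per-point distances
  expect_identical(residuals(fit), fit$distance$distances)
  expect_output(print(fit), "contour-to-mesh")
  s <- summary(fit)
  expect_equal(s$volume_ml, v)
})

test_that("ellipsoid phantom round trip stays within 7% volume error", {
  spec <- phantom_spec("ellipsoid", in_plane_noise_sd = 0)
  m <- make_phantom(spec)
  fit <- suppressWarnings(reconstruct(slice_to_contours(m, spec)))
  expect_lt(fit$distance$mean, 0.5)
  expect_lt(abs(enclosed_volume(fit$mesh) / enclosed_volume(m) - 1), 0.07)
})

test_that("reconstruction copes with in-plane contour noise", {
  spec <- phantom_spec("sphere", size = 30, in_plane_noise_sd = 0.5, seed = 9L)
  m <- make_phantom(spec)
  fit <- suppressWarnings(reconstruct(slice_to_contours(m, spec)))
  # noise sd 0.5 mm: the surface cannot fit noisy contours to zero, but the
  # fit must stay within a couple of noise sds
  expect_lt(fit$distance$mean, 1.5)
  expect_lt(abs(enclosed_volume(fit$mesh) - 113.097) / 113.097, 0.08)
})
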