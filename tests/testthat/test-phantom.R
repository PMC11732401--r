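test_that("phantom meshes are closed, analytic in volume, and deterministic", {
  sp <- make_phantom(phantom_spec("sphere", size = 30))
  expect_lt(abs(enclosed_volume(sp) - 113.097) / 113.097, 0.005)
  el <- make_phantom(phantom_spec("ellipsoid", size = c(30, 25, 20)))
  expect_lt(abs(enclosed_volume(el) - 4 / 3 * pi * 30 * 25 * 20 / 1000) /
              (4 / 3 * pi * 15), 0.005)
  at1 <- make_phantom(phantom_spec("blended_atrium", seed = 3L))
  at2 <- make_phantom(phantom_spec("blended_atrium", seed = 3L))
  expect_identical(at1$vertices, at2$vertices)
  expect_identical(at1$faces, at2$faces)
  expect_true(is_closed_mesh(at1))
  expect_identical(euler_characteristic(at1), 2L)
  # the blended atrium exceeds its ellipsoid body volume (stubs + pouch)
  body <- 4 / 3 * pi * 32 * 28 * 24 / 1000
  expect_gt(enclosed_volume(at1), body)
})

test_that("slicing a sphere gives circles of the analytic radius", {
  m <- sphere_mesh(30, 4L)
  spec <- phantom_spec("sphere", size = 30, in_plane_noise_sd = 0)
  cs <- slice_to_contours(m, spec)
  z <- vapply(cs$contours, function(ct) ct$pose$origin[3], 0)
  expect_true(all(diff(z) == 8))
  for (j in seq_along(z)) {
    r <- sqrt(rowSums(cs$contours[[j]]$points2d^2))
    # facet chords keep intersection points marginally inside the sphere
    # the in-plane radial chord deficit grows near the poles (facet sagitta
    # divided by the sine of the polar angle)
    expect_lt(max(abs(r - sqrt(900 - z[j]^2))), 0.1)
  }
  expect_false(is.null(cs$transverse))
  expect_identical(cs$transverse$pose$plane_label, "transverse")
})

test_that("in-plane jitter has the half-normal radial deviation", {
  m <- sphere_mesh(30, 4L)
  spec <- phantom_spec("sphere", size = 30, in_plane_noise_sd = 0.5,
                       seed = 21L)
  cs <- slice_to_contours(m, spec)
  dev <- unlist(lapply(seq_along(cs$contours), function(j) {
    z <- cs$contours[[j]]$pose$origin[3]
    r <- sqrt(rowSums(cs$contours[[j]]$points2d^2))
    r - sqrt(900 - z^2)
  }))
  # radial deviation of 2D Gaussian jitter ~ projection: mean |dev| close to
  # sd * sqrt(2/pi)
  expect_equal(mean(abs(dev)), 0.5 * sqrt(2 / pi), tolerance = 0.15)
  # same seed reproduces identical contours
  cs2 <- slice_to_contours(m, spec)
  expect_identical(cs$contours[[1]]$points2d, cs2$contours[[1]]$points2d)
})

test_that("sampled clouds follow the layer, noise and outlier spec", {
  m <- sphere_mesh(30, 3L)
  clean <- sample_cloud(m, cloud_spec(n_points = 2000L, surface_noise_sd = 0,
                                      seed = 22L))
  d <- mesh_closest_points(m, clean)$dist
  expect_lt(max(d), 1e-6)   # samples lie exactly on the faceted surface

  dual <- sample_cloud(m, cloud_spec(n_points = 4000L, surface_noise_sd = 0,
                                     epi_fraction = 0.5, epi_offset = 2,
                                     seed = 23L))
  r <- sqrt(rowSums(dual^2))
  expect_equal(mean(r > 31), 0.5, tolerance = 0.03)   # bimodal at 0 / +2 mm
  expect_equal(median(r[r > 31]) - median(r[r <= 31]), 2, tolerance = 0.1)

  outl <- sample_cloud(m, cloud_spec(n_points = 2000L, outlier_fraction = 0.01,
                                     seed = 24L))
  r2 <- sqrt(rowSums(outl^2))
  expect_equal(mean(abs(r2 - mean(r2)) > 3 * sd(r2)), 0.01, tolerance = 0.005)
  expect_identical(sample_cloud(m, cloud_spec(n_points = 500L, seed = 9L)),
                   sample_cloud(m, cloud_spec(n_points = 500L, seed = 9L)))
})

test_that("synthetic fields have CV in range and contact-boosted PCP rates", {
  m <- sphere_mesh(30, 3L)
  tube <- make_tube(c(33, -20, -20), c(33, 20, 20), 5)
  flds <- make_fields(m, tube, effect = 3, duration_s = 600, seed = 25L)
  cv <- flds$cv_af$values
  expect_gte(min(cv), 0.2)
  expect_lte(max(cv), 1.5)
  pr <- flds$proximity
  expect_gt(sum(pr$contact), 10)
  # long duration: empirical rate ratio approaches the effect
  lia <- flds$lia$values
  ratio <- mean(lia[pr$contact]) / mean(lia[!pr$contact])
  expect_equal(ratio, 3, tolerance = 0.15)
  # determinism
  flds2 <- make_fields(m, tube, effect = 3, duration_s = 600, seed = 25L)
  expect_identical(flds2$lia$values, flds$lia$values)
  expect_error(make_fields(m, tube, effect = 0.5), "effect")
})

test_that("null fields show no contact effect over repeated seeds", {
  m <- sphere_mesh(30, 2L)
  tube <- make_tube(c(33, -20, -20), c(33, 20, 20), 5)
  ps <- vapply(1:60, function(s) {
    f <- make_fields(m, tube, effect = 1, duration_s = 60, seed = s)
    compare_by_contact(f$lia, f$proximity)$p_value
  }, 0)
  # p roughly uniform: rejection rate near alpha
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps < 0.5), 0.25)
})
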