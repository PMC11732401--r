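test_that("rigid transforms validate, apply, compose and invert", {
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
  Rimp <- diag(c(1, 1, -1))
  expect_error(rigid_transform(Rimp, c(0, 0, 0)), "proper")
  T1 <- rigid_transform(rotation_z(30), c(1, 2, 3))
  T2 <- rigid_transform(rotation_z(60), c(-1, 0, 5))
  Tc <- compose(T1, T2)
  expect_equal(rot_angle_deg(Tc$rotation), 90, tolerance = 1e-9)
  x <- c(4, -2, 7)
  expect_equal(as.vector(Tc$rotation %*% x + Tc$translation),
               as.vector(T2$rotation %*% (T1$rotation %*% x + T1$translation) +
                           T2$translation), tolerance = 1e-12)
  ident <- compose(T1, invert_transform(T1))
  expect_lt(rot_angle_deg(ident$rotation), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)
  Tid <- rigid_transform()
  expect_equal(compose(Tid, T1)$rotation, T1$rotation)

  m <- cube_mesh()
  shifted <- apply_transform(m, rigid_transform(diag(3), c(1, 0, 0)))
  expect_equal(colMeans(shifted$vertices) - colMeans(m$vertices), c(1, 0, 0))
  rot <- apply_transform(m, T1)
  expect_equal(enclosed_volume(rot), enclosed_volume(m), tolerance = 1e-12)
  expect_equal(surface_area(rot), surface_area(m), tolerance = 1e-9)
  expect_equal(as.matrix(dist(rot$vertices)), as.matrix(dist(m$vertices)),
               tolerance = 1e-9)
})

test_that("transform files round-trip as JSON and 4x4 matrix", {
  T1 <- rigid_transform(rotation_axis(c(1, 1, 0), 17), c(3.5, -2, 0.25))
  for (fmt in c("json", "matrix")) {
    tmp <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".txt")
    write_transform(T1, tmp, format = fmt)
    T2 <- read_transform(tmp)
    expect_equal(T2$rotation, T1$rotation, tolerance = 1e-12)
    expect_equal(T2$translation, T1$translation, tolerance = 1e-12)
  }
})

test_that("GICP on identical meshes returns the identity", {
  m <- decimate_mesh(sphere_mesh(30, 3L), 800L)
  reg <- generalized_icp(m, m)
  expect_lt(rot_angle_deg(reg$transform$rotation), 1e-4)
  expect_lt(max(abs(reg$transform$translation)), 1e-4)
  expect_lt(reg$rms, 1e-6)
})

test_that("GICP recovers a known rigid motion within 0.5 deg / 0.5 mm", {
  m <- fixture("gicp_mesh", function()
    decimate_mesh(make_phantom(phantom_spec("blended_atrium")), 3000L))
  Tt <- rigid_transform(rotation_z(10), c(15, -5, 3))
  tgt <- apply_transform(m, Tt)
  reg <- generalized_icp(m, tgt)
  expect_lt(rot_angle_deg(t(Tt$rotation) %*% reg$transform$rotation), 0.5)
  expect_lt(sqrt(sum((reg$transform$translation - Tt$translation)^2)), 0.5)
  expect_true(all(diff(reg$cost_trace) <= 1e-12))
})

test_that("GICP tolerates 30% localized vertex removal (appendage excision)", {
  m <- fixture("gicp_mesh", function()
    decimate_mesh(make_phantom(phantom_spec("blended_atrium")), 3000L))
  Tt <- rigid_transform(rotation_z(10), c(15, -5, 3))
  tgt <- apply_transform(m, Tt)
  src <- exclude_regions(m, list(exclusion_region(c(28, 4, 10), 24, "laa")))
  removed <- 1 - nrow(src$vertices) / nrow(m$vertices)
  expect_gt(removed, 0.2)
  reg <- generalized_icp(src, tgt)
  expect_lt(rot_angle_deg(t(Tt$rotation) %*% reg$transform$rotation), 2)
  expect_lt(sqrt(sum((reg$transform$translation - Tt$translation)^2)), 2)
  expect_true(all(diff(reg$cost_trace) <= 1e-12))
})

test_that("recovery error does not grow as the perturbation shrinks", {
  base <- decimate_mesh(sphere_mesh(30, 3L), 600L)
  # break the sphere's symmetry so the pose is identifiable
  base$vertices <- base$vertices * (1 + 0.3 * plogis(base$vertices[, 1] / 10))
  errs <- sapply(c(2, 10, 30), function(mag) {
    mean(sapply(1:10, function(s) {
      set.seed(100 + s)
      ax <- rnorm(3)
      Tt <- rigid_transform(rotation_axis(ax, mag), rnorm(3, sd = mag / 2))
      tgt <- apply_transform(base, Tt)
      tgt$vertices <- tgt$vertices + matrix(rnorm(length(tgt$vertices),
                                                  sd = 0.3),
                                            ncol = 3)
      reg <- generalized_icp(base, tgt)
      rot_angle_deg(t(Tt$rotation) %*% reg$transform$rotation)
    }))
  })
  expect_lte(errs[1], errs[3] + 0.5)
  expect_lte(errs[2], errs[3] + 0.5)
})

test_that("GICP errors when no correspondences fall within the cap", {
  m <- cube_mesh(10)
  big <- cube_mesh(1000)
  cfg <- gicp_config(max_correspondence_distance = 0.5)
  expect_error(generalized_icp(m, big, cfg), "larger threshold")
})
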