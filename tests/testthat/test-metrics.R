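test_that("enclosed volume and area match analytic solids", {
  cb <- cube_mesh(10)
  expect_equal(enclosed_volume(cb), 1.000, tolerance = 1e-12)
  expect_equal(surface_area(cb), 600, tolerance = 1e-9)
  sp <- sphere_mesh(30, 4L)
  expect_lt(abs(enclosed_volume(sp) - 113.097) / 113.097, 0.005)
  expect_lt(abs(surface_area(sp) - 4 * pi * 900) / (4 * pi * 900), 0.005)
  open <- surface_mesh(cb$vertices, cb$faces[-1, ])
  expect_error(enclosed_volume(open), "open")
})

test_that("vertex areas are a barycentric partition of the surface area", {
  for (m in list(cube_mesh(3), sphere_mesh(10, 2L))) {
    w <- vertex_areas(m)
    expect_equal(sum(w), surface_area(m), tolerance = 1e-9)
    expect_true(all(w > 0))
  }
  ico <- atriamesh:::icosphere(0L)   # regular icosahedron: all weights equal
  w <- vertex_areas(ico)
  expect_equal(w, rep(w[1], 12), tolerance = 1e-12)
})

test_that("surface distance matches analytic concentric spheres", {
  a <- sphere_mesh(30, 3L)
  b <- sphere_mesh(33, 3L)
  rep_ <- surface_distance(a, b, "symmetric")
  expect_equal(rep_$mean, 3.0, tolerance = 0.01 * 3)
  expect_lte(rep_$mean, max(rep_$mean_a_to_b, rep_$mean_b_to_a) + 1e-12)
  same <- surface_distance(a, a)
  expect_equal(same$mean, 0, tolerance = 1e-10)
  expect_equal(same$sd, 0, tolerance = 1e-10)
  d_ab <- surface_distance(a, b, "a_to_b")
  expect_identical(length(d_ab$per_point), nrow(a$vertices))
  expect_error(surface_distance(a, surface_mesh(matrix(0, 0, 3),
                                                matrix(0L, 0, 3))), "empty")
})

test_that("exclusion editing removes spheres of faces and can cap holes", {
  m <- sphere_mesh(30, 3L)
  off <- exclusion_region(c(200, 0, 0), 10)
  expect_identical(exclude_regions(m, list(off))$faces, m$faces)

  cap <- exclusion_region(c(0, 0, 30), 8, label = "mitral_valve")
  openm <- exclude_regions(m, list(cap), cap_holes = FALSE)
  expect_gt(boundary_edge_count(openm), 0)
  expect_lte(nrow(openm$vertices), nrow(m$vertices))
  closedm <- exclude_regions(m, list(cap), cap_holes = TRUE)
  expect_true(is_closed_mesh(closedm))
  expect_true(is_oriented_mesh(closedm))
  # removing a small cap and re-capping changes volume by under 2%
  expect_lt(abs(enclosed_volume(closedm) / enclosed_volume(m) - 1), 0.02)
})

test_that("exclusion region JSON sidecar loads", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"label":"mitral_valve","center_mm":[0,0,30],"radius_mm":8},
               {"label":"laa","center_mm":[10,0,0],"radius_mm":5}]', tmp)
  regions <- read_exclusion_regions(tmp)
  expect_length(regions, 2L)
  expect_identical(regions[[1]]$label, "mitral_valve")
  expect_equal(regions[[2]]$radius, 5)
})

test_that("equivalent wall thickness follows (dV * 1000) / A", {
  expect_equal(equivalent_wall_thickness(20, 10, 5000), 2.0)
  expect_equal(equivalent_wall_thickness(10, 10, 5000), 0)
  expect_warning(th <- equivalent_wall_thickness(9, 10, 5000), "negative")
  expect_lt(th, 0)
  expect_error(equivalent_wall_thickness(10, 9, 0), "area_inner")
})

test_that("concentric shells recover the shell thickness end to end", {
  # exact agreement with the analytic shell value (R^3 - r^3) / (3 r^2)
  inner <- sphere_mesh(30, 4L)
  outer <- sphere_mesh(31.9, 4L)
  th <- equivalent_wall_thickness(enclosed_volume(outer),
                                  enclosed_volume(inner),
                                  surface_area(inner))
  expect_lt(abs(th - (31.9^3 - 30^3) / (3 * 30^2)) / th, 0.005)
  # for a thin shell (t << r) the equivalent thickness approximates the
  # geometric thickness; curvature inflates it by ~t/r otherwise
  thin_o <- sphere_mesh(30.5, 4L)
  th2 <- equivalent_wall_thickness(enclosed_volume(thin_o),
                                   enclosed_volume(inner),
                                   surface_area(inner))
  expect_lt(abs(th2 - 0.5) / 0.5, 0.02)
})

test_that("compare_reconstructions reports distance, volumes and ratio", {
  a <- sphere_mesh(30, 3L)
  b <- sphere_mesh(33, 3L)
  comp <- compare_reconstructions(a, b)
  expect_equal(comp$relative_volume_pct,
               100 * enclosed_volume(a) / enclosed_volume(b))
  expect_equal(comp$distance$mean, 3, tolerance = 0.05)
  comp2 <- compare_reconstructions(
    a, b, regions = list(exclusion_region(c(0, 0, 30), 6)))
  expect_true(comp2$volume_a_excluded_ml < comp$volume_a_ml)
})
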