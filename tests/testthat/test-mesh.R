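test_that("surface_mesh validates indices, degenerate faces and manifoldness", {
  v <- diag(3)
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  v4 <- rbind(diag(3), c(1, 1, 1), c(-1, -1, -1))
  f_bad <- rbind(c(1, 2, 3), c(1, 3, 2), c(1, 2, 4), c(1, 2, 5))
  expect_error(surface_mesh(v4, f_bad), "edge-manifold")
})

test_that("closedness, orientation and Euler characteristic are detected", {
  cb <- cube_mesh()
  expect_true(is_closed_mesh(cb))
  expect_true(is_oriented_mesh(cb))
  expect_identical(euler_characteristic(cb), 2L)
  open <- surface_mesh(cb$vertices, cb$faces[-1, ])
  expect_false(is_closed_mesh(open))
  expect_identical(boundary_edge_count(open), 3L)
})

test_that("mesh closest points agree with the all-triangle brute force", {
  m <- sphere_mesh(30, 2L)
  set.seed(42)
  q <- matrix(rnorm(300, sd = 25), ncol = 3)
  fast <- mesh_closest_points(m, q)
  slow <- bf_mesh_distance(m, q)
  expect_equal(fast$dist, slow, tolerance = 1e-10)
})

test_that("largest_component keeps the bigger piece and warns", {
  m1 <- cube_mesh()
  m2 <- sphere_mesh(5, 1L)
  m2$vertices <- sweep(m2$vertices, 2, c(100, 0, 0), `+`)
  both <- surface_mesh(rbind(m1$vertices, m2$vertices),
                       rbind(m1$faces, m2$faces + nrow(m1$vertices)))
  expect_warning(kept <- largest_component(both), "components")
  expect_identical(nrow(kept$vertices), nrow(m2$vertices))
})

test_that("orientation repair restores consistent winding", {
  m <- sphere_mesh(10, 2L)
  bad <- m
  flip <- seq(1, nrow(bad$faces), by = 7)
  bad$faces[flip, ] <- bad$faces[flip, c(1, 3, 2)]
  expect_false(is_oriented_mesh(bad))
  fixed <- orient_outward(orient_consistent(bad))
  expect_true(is_oriented_mesh(fixed))
  expect_equal(enclosed_volume(fixed), enclosed_volume(m), tolerance = 1e-12)
})

test_that("mesh I/O round-trips PLY (ascii + binary), OBJ and STL", {
  m <- sphere_mesh(12, 1L)
  for (ext in c("ply", "obj", "stl")) {
    tmp <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, tmp)
    m2 <- read_mesh(tmp)
    expect_equal(sort(round(as.vector(m2$vertices), 5)),
                 sort(round(as.vector(m$vertices), 5)),
                 tolerance = 1e-4, info = ext)
    expect_equal(surface_area(m2), surface_area(m), tolerance = 1e-5,
                 info = ext)
  }
  tmpb <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, tmpb, binary = TRUE)
  m3 <- read_mesh(tmpb)
  expect_equal(m3$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(m3$faces, m$faces)
  expect_error(read_mesh(withr::local_tempfile(fileext = ".xyz")), "not found")
})
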