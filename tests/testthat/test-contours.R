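test_that("slice poses enforce orthonormal axes and contours reject bad input", {
  expect_error(slice_pose(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0)), "orthogonal")
  expect_error(slice_pose(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0)), "unit")
  pose <- slice_pose(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(contour(rbind(c(0, 0), c(1, 1)), pose), ">= 3 points")
  expect_error(contour(rbind(c(0, 0), c(0, 0), c(1, 1)), pose), "1e-9 mm")
  expect_error(
    contour(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2)), pose,
            check_simple = TRUE), "self-intersecting")
})

test_that("to_global maps in-plane coordinates through the pose", {
  p3 <- rbind(c(1, 2), c(0, 0), c(-1, 4))
  ct <- contour(p3, slice_pose(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(to_global(ct)[1, ], c(1, 2, 0))
  ct8 <- contour(p3, slice_pose(c(0, 0, 8), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(to_global(ct8)[1, ], c(1, 2, 8))
  swapped <- contour(p3, slice_pose(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0)))
  expect_equal(to_global(swapped)[1, ], c(2, 1, 0))
})

test_that("to_global is a per-slice isometry", {
  set.seed(11)
  for (k in 1:5) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    vv <- rnorm(3); vv <- vv - sum(vv * u) * u; vv <- vv / sqrt(sum(vv^2))
    pts <- matrix(rnorm(20), ncol = 2) * 10
    ct <- contour(pts, slice_pose(rnorm(3) * 50, u, vv))
    g <- to_global(ct)
    expect_equal(as.matrix(dist(g)), as.matrix(dist(pts)), tolerance = 1e-9)
  }
})

test_that("contour JSON read/write validates and round-trips to 1e-9 mm", {
  tmp <- withr::local_tempfile(fileext = ".json")
  cs <- two_square_set()
  write_contours(cs, tmp)
  cs2 <- read_contours(tmp)
  expect_length(cs2$contours, 2L)
  for (j in 1:2)
    expect_equal(cs2$contours[[j]]$points2d, cs$contours[[j]]$points2d,
                 tolerance = 1e-9)
  expect_equal(cs2$lid_low, cs$lid_low, tolerance = 1e-9)

  one <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  one$slices <- one$slices[1]
  tmp1 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(one, tmp1, auto_unbox = TRUE, digits = NA)
  expect_error(read_contours(tmp1), ">= 2 contours")

  bad <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  bad$slices[[1]]$points <- bad$slices[[1]]$points[1:2]
  tmpb <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, tmpb, auto_unbox = TRUE, digits = NA)
  expect_error(read_contours(tmpb), "points")

  writeLines("{not json", tmpb)
  expect_error(read_contours(tmpb), "malformed")
})

test_that("lids must lie beyond the extreme contours", {
  expect_error(
    contour_set(list(square_contour(10, 0), square_contour(10, 8)),
                lid_low = c(5, 5, 2), lid_high = c(5, 5, 12)),
    "lid_low")
})

test_that("resample_contour places K points at equal arc length", {
  sq <- square_contour(10)
  rs <- resample_contour(sq, 4L)
  expect_equal(rs$points2d, sq$points2d, tolerance = 1e-12)
  rs8 <- resample_contour(sq, 8L)
  seg <- sqrt(rowSums((rs8$points2d -
                         rs8$points2d[c(2:8, 1), ])^2))
  expect_equal(seg, rep(5, 8), tolerance = 1e-9)
  expect_error(resample_contour(sq, 2L), "K must be >= 3")

  circ <- circle_contour(25, n = 720)
  rs360 <- resample_contour(circ, 360L)
  per <- sum(sqrt(rowSums((rs360$points2d -
                             rs360$points2d[c(2:360, 1), ])^2)))
  expect_lt(abs(per - 2 * pi * 25) / (2 * pi * 25), 1e-4)

  # arc-length spacing has negligible coefficient of variation
  seg <- sqrt(rowSums((rs360$points2d - rs360$points2d[c(2:360, 1), ])^2))
  expect_lt(sd(seg) / mean(seg), 1e-6)
})

test_that("resample_contour normalises winding to counter-clockwise", {
  cw <- contour(rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0)),
                slice_pose(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  rs <- resample_contour(cw, 4L)
  expect_gt(atriamesh:::polygon_area2(rs$points2d), 0)
  expect_equal(rs$points2d[1, ], c(0, 0))
})

test_that("align_axial_stack recovers a known slice shift and is idempotent", {
  cs <- sphere_contours()
  shifted <- cs
  j <- 3L
  ct <- shifted$contours[[j]]
  shifted$contours[[j]] <- contour(sweep(ct$points2d, 2, c(4, 0), `+`),
                                   ct$pose)
  aligned <- align_axial_stack(shifted)
  corr <- attr(aligned, "corrections")
  expect_lt(abs(corr[j, 1] + 4), 0.5)
  expect_lt(abs(corr[j, 2]), 0.5)
  # slices already consistent receive (near) zero corrections
  ok <- setdiff(seq_len(nrow(corr)), j)
  expect_lt(max(abs(corr[ok, ])), 0.2)
  # second pass changes nothing
  again <- align_axial_stack(aligned)
  expect_lt(max(abs(attr(again, "corrections"))), 0.05)
})

test_that("align_axial_stack warns and returns input when nothing crosses", {
  cs <- two_square_set()
  high <- contour(rbind(c(0, 100), c(10, 100), c(5, 110)),
                  slice_pose(c(0, 5, 0), c(1, 0, 0), c(0, 0, 1), "transverse"))
  expect_warning(out <- align_axial_stack(cs, high), "does not cross")
  expect_equal(out$contours[[1]]$points2d, cs$contours[[1]]$points2d)
})
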