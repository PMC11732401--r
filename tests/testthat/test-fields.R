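test_that("vertex fields validate values and round-trip CSV", {
  expect_error(vertex_field(c(-1, 0, 1), "lia"), ">= 0")
  f <- vertex_field(c(0.5, 1.2, NA, 0.1), "cv_af")
  expect_identical(f$units, "m/s")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_vertex_field(f, tmp)
  f2 <- read_vertex_field(tmp)
  expect_identical(f2$kind, "cv_af")
  expect_equal(f2$values[c(1, 2, 4)], f$values[c(1, 2, 4)])
})

test_that("nearest-neighbour transfer follows vertex permutations", {
  m <- sphere_mesh(10, 2L)
  vals <- seq_len(nrow(m$vertices)) / 10
  f <- vertex_field(vals, "lia")
  expect_identical(nn_transfer(f, m, m)$values, vals)
  set.seed(12)
  perm <- sample.int(nrow(m$vertices))
  m2 <- m
  m2$vertices <- m$vertices[perm, ]
  expect_identical(nn_transfer(f, m, m2)$values, vals[perm])
  one <- m
  one$vertices <- m$vertices[5, , drop = FALSE]
  expect_identical(nn_transfer(f, m, one)$values, vals[5])
  expect_error(nn_transfer(vertex_field(1:3, "ff"), m, m), "does not match")
})

test_that("area histograms conserve surface area and respect the CV clip", {
  m <- sphere_mesh(10, 2L)
  nv <- nrow(m$vertices)
  const <- vertex_field(rep(0.7, nv), "cv_af")
  h <- area_histogram(const, m, bins = seq(0, 1.5, by = 0.1))
  expect_equal(sum(h$area), surface_area(m), tolerance = 1e-9)
  expect_equal(max(h$area), surface_area(m), tolerance = 1e-9)  # one bin holds all

  # clip_max below all values excludes everything
  h0 <- area_histogram(const, m, bins = seq(0, 1.5, 0.1), clip_max = 0.5)
  expect_equal(sum(h0$area), 0)
  expect_equal(h0$excluded_area, surface_area(m), tolerance = 1e-9)

  # default CV clip at 1.5 m/s excludes faster vertices
  fast <- vertex_field(c(rep(0.7, nv - 10), rep(2, 10)), "cv_af")
  hf <- area_histogram(fast, m, bins = seq(0, 1.5, 0.1))
  expect_equal(sum(hf$area) + hf$excluded_area, surface_area(m),
               tolerance = 1e-9)
  expect_gt(hf$excluded_area, 0)

  # two-value field on a uniform planar grid splits area by vertex count
  n <- 21L
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  gid <- function(i, j) (j - 1L) * n + i
  fgrid <- do.call(rbind, lapply(seq_len(n - 1L), function(j)
    do.call(rbind, lapply(seq_len(n - 1L), function(i)
      rbind(c(gid(i, j), gid(i + 1L, j), gid(i, j + 1L)),
            c(gid(i + 1L, j), gid(i + 1L, j + 1L), gid(i, j + 1L)))))))
  grid_mesh <- surface_mesh(cbind(g$x, g$y, 0), fgrid)
  # split by row halves: boundary-vertex area deficits cancel between halves
  vals <- ifelse(g$y <= (n + 1) / 2, 0.25, 0.75)
  vals[g$y == (n + 1) / 2] <- 0.25
  half <- vertex_field(vals, "lia")
  hh <- area_histogram(half, grid_mesh, bins = c(0, 0.5, 1))
  frac_low <- mean(vals < 0.5)
  expect_equal(hh$area[1] / sum(hh$area), frac_low, tolerance = 0.01)
  expect_error(area_histogram(const, m, bins = c(1, 1, 2)), "increasing")
})

test_that("paired correlations match analytic and brute-force rank results", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.7, 0.3, 0.55, 0.8)
  lin <- paired_correlation(x, 2 * x + 1, "pearson")
  expect_equal(lin$estimate, 1, tolerance = 1e-12)
  mono <- paired_correlation(x, exp(3 * x), "spearman")
  expect_equal(mono$estimate, 1, tolerance = 1e-12)
  expect_lt(paired_correlation(x, exp(3 * x), "pearson")$estimate, 1)

  set.seed(13)
  a <- round(rnorm(30), 1)  # ties likely
  b <- round(a + rnorm(30), 1)
  got <- paired_correlation(a, b, "spearman")
  expect_equal(got$estimate, stats::cor(bf_avg_rank(a), bf_avg_rank(b)),
               tolerance = 1e-12)
  # missing values are deleted pairwise
  a[3] <- NA
  got2 <- paired_correlation(a, b, "pearson")
  expect_identical(got2$n, 29L)
  expect_error(paired_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("structure distances match analytic configurations and brute force", {
  # large flat quad at z = 0
  quad <- surface_mesh(rbind(c(-100, -100, 0), c(100, -100, 0),
                             c(100, 100, 0), c(-100, 100, 0)),
                       rbind(c(1, 2, 3), c(1, 3, 4)))
  la <- surface_mesh(rbind(c(0, 0, 5), c(1, 0, 5), c(0, 1, 6)),
                     rbind(c(1, 2, 3)))
  pr <- structure_distance(la, quad)
  expect_equal(pr$distances, c(5, 5, 6), tolerance = 1e-12)

  s1 <- sphere_mesh(1, 3L)
  s2 <- sphere_mesh(1, 3L)
  s2$vertices <- sweep(s2$vertices, 2, c(10, 0, 0), `+`)
  pr2 <- structure_distance(s1, s2)
  expect_true(all(pr2$distances >= 8 - 0.01))
  expect_equal(min(pr2$distances), 8, tolerance = 0.01)

  m <- sphere_mesh(5, 2L)
  st <- cube_mesh(4)
  set.seed(14)
  idx <- sample.int(nrow(m$vertices), 50)
  sub <- m
  sub$vertices <- m$vertices[idx, , drop = FALSE]
  pr3 <- structure_distance(sub, st)
  expect_equal(pr3$distances, bf_mesh_distance(st, sub$vertices),
               tolerance = 1e-10)
  expect_error(structure_distance(m, surface_mesh(matrix(0, 0, 3),
                                                  matrix(0L, 0, 3))), "empty")
})

test_that("contact masks are inclusive at the threshold and union over structures", {
  pr <- structure(list(distances = c(2.9, 3.0, 3.1), structure_label = "a",
                       contact = NULL, threshold_mm = NULL),
                  class = "proximity_result")
  cm <- contact_mask(pr, 3)
  expect_identical(cm$contact, c(TRUE, TRUE, FALSE))
  cm0 <- contact_mask(pr, 0)
  expect_identical(cm0$contact, c(FALSE, FALSE, FALSE))
  prb <- structure(list(distances = c(10, 10, 1), structure_label = "b",
                        contact = NULL, threshold_mm = NULL),
                   class = "proximity_result")
  u <- contact_mask(list(pr, prb), 3)
  expect_identical(u$contact, c(TRUE, TRUE, TRUE))
  expect_equal(u$distances, c(2.9, 3.0, 1))
})

test_that("Mann-Whitney contact comparison matches full enumeration", {
  gc <- compare_by_contact(vertex_field(c(1, 2, 3, 4, 5, 6), "lia"),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(unname(gc$U), 0)
  expect_equal(gc$p_value, 0.1, tolerance = 1e-12)
  expect_equal(gc$median_contact, 2)
  expect_equal(gc$median_noncontact, 5)

  set.seed(15)
  for (k in 1:5) {
    n1 <- sample(2:5, 1)
    n0 <- sample(2:5, 1)
    v <- sample(1:50, n1 + n0)   # tie-free
    contact <- c(rep(TRUE, n1), rep(FALSE, n0))
    got <- compare_by_contact(vertex_field(v, "ff"), contact)
    oracle <- bf_mann_whitney(v[contact], v[!contact])
    expect_equal(unname(got$U), oracle$U)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-9)
  }

  same <- compare_by_contact(vertex_field(c(1:5, 1:5), "ff"),
                             rep(c(TRUE, FALSE), each = 5))
  expect_gt(same$p_value, 0.9)
  expect_equal(same$median_contact, same$median_noncontact)
  expect_error(compare_by_contact(vertex_field(1:3, "ff"), rep(TRUE, 3)),
               "non-contact group")
})

test_that("paired t equals the closed form and rejects zero variance", {
  x <- c(10.2, 11.5, 9.8, 12.0)
  y <- c(9.9, 10.8, 9.9, 11.1)
  got <- paired_t_test(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$df, 3)
  expect_error(paired_t_test(x, x), "zero variance")
  # p shrinks as jitter around a constant difference shrinks
  set.seed(16)
  ps <- sapply(c(0.5, 0.05, 0.005), function(s)
    paired_t_test(x + 3 + rnorm(4, sd = s), x)$p_value)
  expect_true(all(diff(ps) < 0))
})
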