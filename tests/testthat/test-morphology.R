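test_that("physical dilation matches hand-derived neighbourhoods", {
  # identity at tolerance 0
  set.seed(1)
  m <- random_mask(c(7, 7, 4), c(1, 1, 1), p = 0.2)
  expect_identical(dilate_physical(m, 0)$data, m$data)

  # single voxel, isotropic spacing, tolerance 1 -> centre + 6 face neighbours
  s <- binary_volume(array(FALSE, c(5, 5, 5)))
  s$data[3, 3, 3] <- TRUE
  d <- dilate_physical(s, 1)
  expect_equal(bv_count(d), 7)
  expect_identical(d$data, brute_dilate(s, 1)$data)

  # single voxel, (0.5, 0.5, 2.5) mm spacing, tolerance 2.5 mm:
  # in-plane disc of radius 5 voxels plus one voxel one slice up and down
  a <- aniso(c(21, 21, 5))
  a$data[11, 11, 3] <- TRUE
  d <- dilate_physical(a, 2.5)
  expect_identical(d$data, brute_dilate(a, 2.5)$data)
  expect_equal(sum(d$data[, , 2]), 1)
  expect_equal(sum(d$data[, , 4]), 1)
  expect_equal(sum(d$data[, , 1]), 0)
  in_plane <- sum(d$data[, , 3])
  # physical disc: (0.5 dx)^2 + (0.5 dy)^2 <= 2.5^2, i.e. dx^2 + dy^2 <= 25
  disc <- sum(outer((-10:10)^2, (-10:10)^2, `+`) <= 25)
  expect_equal(in_plane, disc)

  expect_error(dilate_physical(s, -1), "non-negative")
})

test_that("voxel-unit ball dilation equals offset enumeration", {
  s <- binary_volume(array(FALSE, c(13, 13, 13)), c(0.7, 0.7, 3))
  s$data[7, 7, 7] <- TRUE
  expect_identical(dilate_voxel(s, 0)$data, s$data)
  expect_equal(bv_count(dilate_voxel(s, 1)), 7)
  # radius 5: all integer offsets with squared norm <= 25 (spacing ignored)
  off <- expand.grid(x = -6:6, y = -6:6, z = -6:6)
  n5 <- sum(off$x^2 + off$y^2 + off$z^2 <= 25)
  expect_equal(bv_count(dilate_voxel(s, 5)), n5)
  expect_error(dilate_voxel(s, -2), "non-negative")
})

test_that("closing fills gaps, is extensive and idempotent", {
  # convex solid away from the border is unchanged
  cube <- binary_volume(array(FALSE, c(16, 16, 16)))
  cube$data[6:11, 6:11, 6:11] <- TRUE
  expect_identical(closing_voxel(cube, 3)$data, cube$data)

  # two cubes with a 1-voxel gap: the gap between them closes
  two <- binary_volume(array(FALSE, c(14, 9, 9)))
  two$data[3:5, 4:6, 4:6] <- TRUE
  two$data[7:9, 4:6, 4:6] <- TRUE
  cl <- closing_voxel(two, 2)
  expect_true(cl$data[6, 5, 5])      # centre of the gap bridges
  expect_gt(bv_count(cl), bv_count(two))
  expect_true(all(cl$data[two$data]))

  # extensive + idempotent on random blobby masks
  set.seed(31)
  for (i in 1:5) {
    m <- random_mask(c(12, 12, 8), c(1, 1, 1), p = 0.15)
    c1 <- closing_voxel(m, 2)
    expect_true(all(c1$data[m$data]))
    expect_identical(closing_voxel(c1, 2)$data, c1$data)
  }
})

test_that("erosion is the dual of dilation away from the border", {
  set.seed(41)
  m <- binary_volume(array(FALSE, c(12, 12, 12)))
  m$data[4:9, 4:9, 4:9] <- TRUE
  er <- erode_voxel(m, 2)
  # every surviving voxel has its whole ball inside the cube
  expect_true(all(er$data[6:7, 6:7, 6:7]))
  expect_equal(bv_count(er), sum(er$data))
  expect_true(all(m$data[er$data]))
  # physical erosion shrinks a ball by the tolerance
  b <- fixture_ball(c(21, 21, 9), c(1, 1, 1), c(11, 11, 5), 6)
  e <- erode_physical(b, 2)
  expect_true(all(b$data[e$data]))
  expect_true(bv_count(e) > 0)
  expect_identical(erode_physical(b, 0)$data, b$data)
})

test_that("dilation agrees with the all-pairs oracle on random grids", {
  set.seed(51)
  spacings <- list(c(1, 1, 1), c(0.5, 0.5, 2.5))
  for (i in 1:12) {
    sp <- spacings[[1 + (i %% 2)]]
    shp <- c(sample(4:16, 1), sample(4:16, 1), sample(2:8, 1))
    m <- random_mask(shp, sp, p = runif(1, 0, 0.2))
    for (tol in c(0, 1, 2.5, 5)) {
      expect_identical(dilate_physical(m, tol)$data,
                       brute_dilate(m, tol)$data)
    }
  }
})

test_that("dilation is monotone in the tolerance and extensive", {
  set.seed(61)
  for (i in 1:6) {
    m <- random_mask(c(10, 10, 6), c(0.5, 0.5, 2.5), p = 0.1)
    d1 <- dilate_physical(m, 1); d2 <- dilate_physical(m, 3)
    expect_true(all(d1$data[m$data]))
    expect_true(all(d2$data[d1$data]))
    v1 <- dilate_voxel(m, 1); v2 <- dilate_voxel(m, 2)
    expect_true(all(v2$data[v1$data]))
  }
})

test_that("explicit structuring elements reproduce the distance threshold", {
  expect_error(structuring_element("annulus-physical", 2, 3), "inner_radius")
  expect_error(structuring_element("ball-voxel", -1), ">= 0")
  b <- fixture_ball(c(17, 17, 7), c(1, 1, 1), c(9, 9, 4), 3)
  el <- structuring_element("ball-physical", 2)
  expect_identical(dilate_with_element(b, el)$data,
                   dilate_physical(b, 2)$data)
  # annulus with the same outer radius dilates a solid region identically
  an <- structuring_element("annulus-physical", 2, 1)
  expect_identical(dilate_with_element(b, an)$data,
                   dilate_physical(b, 2)$data)
})
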