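# constructed case: two lesions on an anisotropic grid, one biopsy-positive
gt_fixture <- function(gap_vox = 10) {
  shape <- c(44, 20, 8); sp <- c(0.5, 0.5, 2.5)
  manual <- binary_volume(array(FALSE, shape), sp)
  manual$data[4:9, 8:13, 4:5] <- TRUE                 # lesion A
  manual$data[(24:29) + (gap_vox - 10), 8:13, 4:5] <- TRUE  # lesion B
  labels <- array(0L, shape)
  list(shape = shape, sp = sp, manual = manual, labels = labels)
}

test_that("biopsy outcomes are validated", {
  f <- gt_fixture()
  f$labels[5, 10, 4] <- 1L
  expect_error(biopsy_set(f$labels, "weird", f$sp), "unknown biopsy outcome")
  expect_error(biopsy_set(f$labels, c("benign", "benign"), f$sp),
               "one outcome per biopsy")
})

test_that("lesions are confirmed by intersection or proximity, never by benign biopsies", {
  f <- gt_fixture()
  f$labels[5, 10, 4] <- 1L     # inside lesion A
  f$labels[34, 10, 4] <- 2L    # 2.5 mm right of lesion B (5 voxels x 0.5 mm)
  bs <- biopsy_set(f$labels, c("malignant", "malignant"), f$sp)
  conf <- confirm_lesions(f$manual, bs, radius = 5)
  expect_equal(conf$lesions$n, 2)
  expect_setequal(conf$table$rule, c("intersect", "within-radius"))
  expect_false(conf$inconsistent)

  # radius 0 reduces confirmation to pure intersection
  conf0 <- confirm_lesions(f$manual, bs, radius = 0)
  expect_equal(conf0$lesions$n, 1)
  expect_equal(conf0$table$rule[1], "intersect")

  # benign and undetermined biopsies never confirm
  bs2 <- biopsy_set(f$labels, c("benign", "undetermined"), f$sp)
  conf2 <- confirm_lesions(f$manual, bs2, radius = 5)
  expect_equal(conf2$lesions$n, 0)
  expect_equal(bv_count(conf2$mask), 0)
})

test_that("the confirmation radius is an inclusive surface distance", {
  f <- gt_fixture()
  # lesion B right edge at x index 29; malignant biopsy 4.0 mm away
  f$labels[37, 10, 4] <- 1L
  bs <- biopsy_set(f$labels, "malignant", f$sp)
  conf <- confirm_lesions(f$manual, bs, radius = 5)
  expect_true("within-radius" %in% conf$table$rule)
  # at 6.0 mm it is out of reach and the case becomes inconsistent
  f2 <- gt_fixture()
  f2$labels[29 + 12, 10, 4] <- 1L
  bs2 <- biopsy_set(f2$labels, "malignant", f2$sp)
  conf2 <- confirm_lesions(f2$manual, bs2, radius = 5)
  expect_false(any(conf2$table$rule == "within-radius"))
  expect_true(conf2$inconsistent)
  # exactly at 5.0 mm (10 voxels in-plane) the boundary is inclusive
  f3 <- gt_fixture()
  f3$labels[39, 10, 4] <- 1L   # 10 voxels from edge voxel 29 -> 5.0 mm
  bs3 <- biopsy_set(f3$labels, "malignant", f3$sp)
  conf3 <- confirm_lesions(f3$manual, bs3, radius = 5)
  expect_true("within-radius" %in% conf3$table$rule)
})

test_that("confirmed ground truth never adds voxels and recovers planted truth", {
  cfg <- phantom_config(seed = 5)
  for (i in c(80, 100, 119)) {   # one- and two-lesion cases
    case <- generate_case(cfg, i)
    conf <- confirm_lesions(case$manual, case$biopsies, radius = 5)
    expect_true(all(case$manual$data[conf$mask$data]))
    # exactly the designated lesions are confirmed
    expect_equal(conf$lesions$n, case$meta$n_lesions)
    expect_identical(conf$mask$data, case$gt$data)
  }
})

test_that("lesion zone assignment is by majority with PZ tie-break", {
  shape <- c(20, 20, 4)
  tz <- binary_volume(array(FALSE, shape))
  pz <- binary_volume(array(FALSE, shape))
  tz$data[1:10, , ] <- TRUE
  pz$data[11:20, , ] <- TRUE
  zones <- zone_pair(tz, pz)
  les <- binary_volume(array(FALSE, shape))
  les$data[5:14, 2, 2] <- TRUE     # 6 voxels TZ, 4 PZ
  les$data[9:12, 6, 2] <- TRUE     # 2 TZ, 2 PZ tie
  les$data[16:18, 10, 2] <- TRUE   # pure PZ
  lm <- connected_components(les, 26)
  z <- assign_lesion_zones(lm, zones)
  expect_equal(nrow(z), 3)
  expect_equal(z$primary[z$tz_voxels == 6], "TZ")
  expect_equal(z$primary[z$tz_voxels == 2 & z$pz_voxels == 2], "PZ")
  expect_equal(z$primary[z$tz_voxels == 0], "PZ")
  # a lesion outside both zones warns and gets "none"
  far <- binary_volume(array(FALSE, shape))
  far$data[3, 15, 4] <- TRUE
  tz0 <- binary_volume(array(FALSE, shape)); pz0 <- tz0
  expect_warning(z2 <- assign_lesion_zones(connected_components(far),
                                           zone_pair(tz0, pz0)),
                 "outside both zones")
  expect_equal(z2$primary, "none")
})

test_that("lesion size statistics are physical volumes", {
  v <- aniso(c(10, 10, 4))
  v$data[1:4, 1:4, 1] <- TRUE      # 16 voxels -> 10 mm^3
  v$data[8:10, 8:10, 3:4] <- TRUE  # 18 voxels -> 11.25 mm^3
  s <- lesion_size_stats(connected_components(v, 26))
  expect_equal(s$n, 2)
  expect_equal(s$min, 10)
  expect_equal(s$max, 11.25)
  expect_equal(s$mean, 10.625)
  expect_equal(s$median, 10.625)
  s0 <- lesion_size_stats(connected_components(aniso(c(4, 4, 2))))
  expect_equal(s0$n, 0)
  expect_true(is.na(s0$mean))
})
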