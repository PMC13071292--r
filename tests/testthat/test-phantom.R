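# a small cohort config shared across phantom tests (full default grid,
# fewer cases, to keep runtimes short)
small_cfg <- function(...) phantom_config(n_cases = 119, seed = 17, ...)

test_that("case generation is deterministic and order-independent", {
  cfg <- small_cfg()
  a <- generate_case(cfg, 90)
  b <- generate_case(cfg, 90)
  expect_identical(a$gt$data, b$gt$data)
  expect_identical(a$manual$data, b$manual$data)
  expect_identical(a$biopsies$labels, b$biopsies$labels)
  expect_identical(lapply(a$predictions, `[[`, "data"),
                   lapply(b$predictions, `[[`, "data"))
  # generating another case in between changes nothing
  invisible(generate_case(cfg, 5))
  c <- generate_case(cfg, 90)
  expect_identical(a$gt$data, c$gt$data)
  # a different base seed changes the case
  d <- generate_case(phantom_config(n_cases = 119, seed = 18), 90)
  expect_false(identical(a$gt$data, d$gt$data))
})

test_that("cohort composition mirrors the configured prevalence", {
  cfg <- small_cfg()
  profiles <- vapply(seq_len(cfg$n_cases),
                     function(i) zonedice:::case_profile(cfg, i), integer(1))
  expect_equal(sum(profiles == 0), 77)
  expect_equal(sum(profiles > 0), 42)
  expect_equal(sum(profiles == 1), 36)
  expect_equal(sum(profiles == 2), 6)
  # spot-check generated cases agree with their profile
  for (i in c(1, 77, 78, 114, 119)) {
    case <- generate_case(cfg, i)
    expect_equal(case$gt_lesions$n, profiles[i])
    if (profiles[i] == 0) {
      expect_equal(bv_count(case$gt), 0)
      expect_true(all(case$biopsies$outcomes != "malignant"))
    }
  }
})

test_that("lesion-free configuration empties every ground truth", {
  cfg <- phantom_config(n_cases = 6, n_lesion_free = 6, seed = 23)
  for (case in generate_cohort(cfg)) {
    expect_equal(bv_count(case$gt), 0)
    expect_false(any(case$biopsies$outcomes == "malignant"))
  }
})

test_that("zone faults are controllable", {
  # no faults: zones partition the gland exactly
  clean <- phantom_config(n_cases = 119, gap_width_mm = 0,
                          overlap_width_mm = 0, seed = 29)
  case <- generate_case(clean, 80)
  expect_equal(sum(case$tz_raw$data & case$pz_raw$data), 0)
  expect_identical(case$tz_raw$data | case$pz_raw$data, case$prostate$data)
  # overlap width > 0 creates overlapping zones; gap > 0 leaves a moat
  faulty <- small_cfg()
  case <- generate_case(faulty, 80)
  expect_gt(sum(case$tz_raw$data & case$pz_raw$data), 0)
  expect_gt(sum(case$prostate$data & !(case$tz_raw$data | case$pz_raw$data)), 0)
  # the repair machinery accepts these pairs
  zp <- postprocess_zones(case$pz_raw, case$tz_raw)
  expect_equal(sum(zp$tz$data & zp$pz$data), 0)
})

test_that("planted truth is recoverable from biopsies and degradations", {
  cfg <- small_cfg()
  for (i in c(85, 100, 117)) {
    case <- generate_case(cfg, i)
    # confirmation recovers exactly the designated lesions
    conf <- confirm_lesions(case$manual, case$biopsies, radius = 5)
    expect_identical(conf$mask$data, case$gt$data)
    # per-method: dropped + out-of-zone lesions are missed, spurious sites
    # are spurious, exactly
    for (m in names(case$predictions)) {
      meta <- case$meta$methods[[m]]
      rep <- match_lesions(case$predictions[[m]], case$gt_lesions)
      expect_equal(rep$n_missed,
                   length(meta$dropped) + length(meta$out_of_zone))
      expect_equal(rep$n_spurious, length(meta$spurious_sites))
      expect_equal(which(!rep$detected),
                   sort(c(meta$dropped, meta$out_of_zone)))
    }
  }
})

test_that("degrade_mask honours its identity and extreme settings", {
  cfg <- small_cfg()
  case <- generate_case(cfg, 100)
  gt <- case$gt
  expect_identical(degrade_mask(gt, 0, 0, 0, seed = 1)$data, gt$data)
  expect_equal(bv_count(degrade_mask(gt, 0, 1, 0, seed = 1)), 0)
  # deterministic per seed
  d1 <- degrade_mask(gt, 2, 0.5, 1, seed = 9)
  d2 <- degrade_mask(gt, 2, 0.5, 1, seed = 9)
  expect_identical(d1$data, d2$data)
  m1 <- attr(d1, "degrade_meta")
  expect_equal(m1$dropped, attr(d2, "degrade_meta")$dropped)
  # spurious-only degradation leaves the truth untouched and countable
  d3 <- degrade_mask(gt, 0, 0, 3, seed = 11)
  expect_true(all(d3$data[gt$data]))
  m3 <- attr(d3, "degrade_meta")
  rep <- match_lesions(d3, case$gt_lesions)
  expect_equal(rep$n_spurious, m3$n_spurious)
  expect_equal(rep$n_missed, 0)
})

test_that("boundary jitter within the tolerance is forgiven by the tolerant metric", {
  cfg <- small_cfg()
  found_imperfect <- FALSE
  for (i in c(90, 101, 115)) {
    case <- generate_case(cfg, i)
    pred <- degrade_mask(case$gt, jitter_mm = 2, drop_p = 0,
                         spurious_rate = 0, seed = i)
    oc <- overlap_counts(pred, case$gt, tolerance = 5)
    expect_equal(dsc_tau(oc), 1.0)
    if (dsc(oc) < 1) found_imperfect <- TRUE
  }
  expect_true(found_imperfect)
  # jitter beyond the tolerance strictly lowers the tolerant metric
  case <- generate_case(cfg, 101)
  pred <- degrade_mask(case$gt, jitter_mm = 8, drop_p = 0,
                       spurious_rate = 0, seed = 3)
  oc <- overlap_counts(pred, case$gt, tolerance = 2.5)
  expect_lt(dsc_tau(oc), 1.0)
})

test_that("generated lesion volumes respect the configured range", {
  cfg <- small_cfg()
  vols <- unlist(lapply(c(80, 90, 100, 110, 119), function(i)
    generate_case(cfg, i)$gt_lesions$volumes_mm3))
  expect_true(all(vols > 0))
  # blobs are unions of the target-volume ball with smaller satellites, so
  # sizes stay within a small factor of the configured range
  expect_true(all(vols >= cfg$lesion_volume_mm3[1] / 4))
  expect_true(all(vols <= cfg$lesion_volume_mm3[2] * 4))
})
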