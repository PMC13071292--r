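test_that("fold assignment stratifies exactly and deterministically", {
  # 10 positive + 10 negative, k = 5: every fold gets 2 + 2
  pos <- rep(c(TRUE, FALSE), each = 10)
  f <- assign_folds(pos, k = 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(4L, 5))
  expect_equal(as.integer(table(f[pos])), rep(2L, 5))
  # 42 positive + 77 negative, k = 5: sizes 24,24,24,24,23, positives 9/9/8/8/8
  pos <- rep(c(TRUE, FALSE), c(42, 77))
  f <- assign_folds(pos, k = 5, seed = 3)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(24L, 24L, 24L, 24L, 23L))
  expect_equal(sort(as.integer(table(f[pos])), decreasing = TRUE),
               c(9L, 9L, 8L, 8L, 8L))
  # determinism and seed sensitivity
  expect_identical(f, assign_folds(pos, k = 5, seed = 3))
  expect_false(identical(f, assign_folds(pos, k = 5, seed = 4)))
  expect_error(assign_folds(pos, k = 1), ">= 2")
  expect_error(assign_folds(pos[1:3], k = 5), "exceeds")
})

test_that("metric matrices drop undefined patients listwise", {
  rec <- expand.grid(patient_id = c("a", "b", "c"),
                     method_id = c("m1", "m2"), stringsAsFactors = FALSE)
  rec$dsc_tau <- c(0.5, 0.7, NA, 0.6, 0.8, 0.9)
  rec$dsc <- rec$dsc_tau
  m <- metric_matrix(rec, "dsc_tau")
  expect_equal(rownames(m), c("a", "b"))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["a", "m2"], 0.6)
})

test_that("aggregation returns sample mean and n-1 standard deviation", {
  m <- cbind(m1 = c(0.4, 0.6), m2 = c(0.5, 0.5))
  a <- aggregate_metrics(m)
  expect_equal(a$mean, c(0.5, 0.5))
  expect_equal(a$sd[1], sqrt(sum((c(0.4, 0.6) - 0.5)^2) / 1))  # 0.1414214
  expect_equal(a$sd[2], 0)
  m2 <- cbind(m1 = c(0.4, NA, 0.6))
  expect_equal(aggregate_metrics(m2)$n, 2)
  expect_equal(aggregate_metrics(m2)$mean, 0.5)
})

test_that("Friedman statistic matches base R on tie-free data and is rank-based", {
  set.seed(141)
  for (i in 1:6) {
    m <- matrix(rnorm(8 * 4), 8, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
    ours <- friedman_test(m)
    base <- stats::friedman.test(m)
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
    # invariance under a strictly monotone per-block transform
    m2 <- t(apply(m, 1, function(r) exp(3 * r)))
    colnames(m2) <- colnames(m)
    expect_equal(friedman_test(m2)$statistic, ours$statistic)
  }
  # identical columns: statistic 0, p 1
  id <- matrix(rep(c(0.2, 0.5, 0.9), 3), 3, 3)
  expect_equal(friedman_test(id)$statistic, 0)
  expect_equal(friedman_test(id)$p_value, 1)
  # dominant column on a hand-ranked 3x4 fixture: classical formula
  dom <- cbind(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8), c = c(9, 10, 11, 12))
  # ranks are 1,2,3 in every block: chi2 = 12/(4*3*4)*(4^2+8^2+12^2) - 3*4*4
  expect_equal(friedman_test(dom)$statistic,
               12 / (4 * 3 * 4) * (16 + 64 + 144) - 3 * 4 * 4)
  expect_error(friedman_test(dom[1, , drop = FALSE]), ">= 2")
})

test_that("Conover post hoc matches the scalar textbook reference to 1e-9", {
  set.seed(151)
  for (i in 1:5) {
    m <- matrix(rnorm(6 * 3) + rep(c(0, 0.5, 1), each = 6), 6, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    res <- conover_posthoc(m, adjust = "none")
    ref <- conover_reference(m)
    expect_equal(res$statistic, ref$T2, tolerance = 1e-12)
    pw <- res$pairwise
    for (r in seq_len(nrow(pw))) {
      i1 <- match(pw$method_a[r], colnames(m))
      i2 <- match(pw$method_b[r], colnames(m))
      expect_equal(pw$p_raw[r], ref$p[i1, i2], tolerance = 1e-9)
    }
  }
  # frozen fixture: regression anchor for the full chain
  fix <- matrix(c(0.62, 0.71, 0.55, 0.48, 0.80, 0.66,
                  0.65, 0.78, 0.60, 0.55, 0.79, 0.72,
                  0.70, 0.82, 0.68, 0.62, 0.85, 0.75),
                nrow = 6, dimnames = list(NULL, c("m1", "m2", "m3")))
  ref <- conover_reference(fix)
  res <- conover_posthoc(fix, adjust = "none")
  expect_equal(res$pairwise$p_raw,
               c(ref$p[1, 2], ref$p[1, 3], ref$p[2, 3]), tolerance = 1e-9)
  # identical columns: every pairwise p is 1
  id <- matrix(rep(c(0.2, 0.5, 0.9, 0.4), 3), 4, 3)
  expect_true(all(conover_posthoc(id)$pairwise$p_raw == 1))
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  m <- matrix(rnorm(6 * 3), 6, 3)
  res <- conover_posthoc(m, adjust = "bh")
  expect_equal(res$pairwise$p_adjusted,
               p.adjust(res$pairwise$p_raw, "BH"))
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adjusted <= 1))
  # the classic hand case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
})

test_that("permuting method columns permutes pairwise results consistently", {
  set.seed(161)
  m <- matrix(rnorm(6 * 3) + rep(c(0, 1, 2), each = 6), 6, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  r1 <- conover_posthoc(m, adjust = "none")$pairwise
  r2 <- conover_posthoc(m[, c(2, 3, 1)], adjust = "none")$pairwise
  key <- function(d) {
    k <- apply(cbind(d$method_a, d$method_b), 1,
               function(x) paste(sort(x), collapse = "-"))
    setNames(d$p_raw, k)[order(k)]
  }
  expect_equal(key(r1), key(r2), tolerance = 1e-12)
})
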