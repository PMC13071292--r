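#' Stratified cross-validation fold assignment
#'
#' Splits patients into `k` folds so that lesion-bearing and lesion-free
#' patients are each distributed as evenly as possible, and total fold sizes
#' differ by at most one. Positives are dealt round-robin to a seeded random
#' fold order; negatives then top folds up to the (as even as possible) target
#' totals. Deterministic for a fixed seed.
#'
#' @param positive logical vector, `TRUE` for lesion-bearing patients.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`, one per patient.
#' @examples
#' f <- assign_folds(rep(c(TRUE, FALSE), c(42, 77)), k = 5, seed = 1)
#' table(f)  # 24 24 24 24 23
#' @export
assign_folds <- function(positive, k = 5, seed = 1) {
  positive <- as.logical(positive)
  n <- length(positive)
  if (k < 2) stop("`k` must be >= 2")
  if (k > n) stop("`k` exceeds the number of patients")
  fold <- integer(n)
  with_seed(as.integer(seed), {
    npos <- sum(positive)
    # even split of positives: sizes differ by <= 1, larger folds first
    pos_sizes <- diff(round(seq(0, npos, length.out = k + 1)))
    pos_sizes <- sort(pos_sizes, decreasing = TRUE)
    tot_sizes <- diff(round(seq(0, n, length.out = k + 1)))
    tot_sizes <- sort(tot_sizes, decreasing = TRUE)
    neg_sizes <- tot_sizes - pos_sizes
    if (any(neg_sizes < 0))
      stop("cannot satisfy stratification: too few negatives per fold")
    fold[sample(which(positive))] <- rep(seq_len(k), times = pos_sizes)
    fold[sample(which(!positive))] <- rep(seq_len(k), times = neg_sizes)
  })
  fold
}

#' Complete blocked metric matrix
#'
#' Builds the patients x methods matrix of one metric from tidy per-patient
#' records, the input of the comparison protocol. Patients with an undefined
#' metric for any method (typically lesion-free patients, whose Dice is
#' undefined) are dropped listwise so the block design is complete.
#'
#' @param records `data.frame` of [evaluate_patient()] rows.
#' @param metric column to use, `"dsc"` or `"dsc_tau"`.
#' @return numeric matrix, rownames patient ids, colnames method ids.
#' @export
metric_matrix <- function(records, metric = c("dsc_tau", "dsc")) {
  metric <- match.arg(metric)
  stopifnot(all(c("patient_id", "method_id", metric) %in% names(records)))
  pts <- unique(records$patient_id)
  mth <- unique(records$method_id)
  m <- matrix(NA_real_, length(pts), length(mth),
              dimnames = list(pts, mth))
  m[cbind(match(records$patient_id, pts),
          match(records$method_id, mth))] <- records[[metric]]
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Per-method mean and standard deviation
#'
#' Column means and sample (n-1) standard deviations over defined values.
#'
#' @param matrix blocked metric matrix (patients x methods); `NA`s ignored.
#' @return `data.frame` with columns `method_id`, `n`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1)
  data.frame(
    method_id = colnames(matrix),
    n = apply(matrix, 2, function(x) sum(!is.na(x))),
    mean = apply(matrix, 2, mean, na.rm = TRUE),
    sd = apply(matrix, 2, sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Within-block (row-wise) average ranks.
block_ranks <- function(matrix) {
  t(apply(matrix, 1, rank))
}

#' Friedman test on a blocked metric matrix
#'
#' Nonparametric test for differences between related groups: patients are
#' blocks, methods are treatments, and the test asks whether the mean
#' within-patient ranks of the methods differ. The statistic uses the
#' tie-corrected form
#' `T2 = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A1 - C1)` with `A1` the sum of
#' squared ranks and `C1 = n k (k+1)^2 / 4`, which reduces to the classical
#' `12/(nk(k+1)) sum R_j^2 - 3n(k+1)` when there are no ties, and is compared
#' to a chi-square with `k-1` degrees of freedom. When every block ranks all
#' methods identically equal (all columns equal), the statistic is 0 and p is
#' 1.
#'
#' @param matrix complete numeric matrix, blocks (patients) x methods.
#' @param alpha significance level carried into the result (default 0.05).
#' @return object of class `zonedice_test`: list with `method`, `statistic`,
#'   `df`, `p_value`, `rank_sums`, `alpha`, `significant`.
#' @export
friedman_test <- function(matrix, alpha = 0.05) {
  stopifnot(is.matrix(matrix))
  if (anyNA(matrix)) stop("matrix must be complete; see metric_matrix()")
  n <- nrow(matrix); k <- ncol(matrix)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 methods")
  r <- block_ranks(matrix)
  R <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((R - n * (k + 1) / 2)^2)
  stat <- if (A1 == C1) 0 else num / (A1 - C1)
  p <- if (stat == 0) 1 else pchisq(stat, df = k - 1, lower.tail = FALSE)
  structure(list(method = "Friedman rank sum test (tie-corrected)",
                 statistic = stat, df = k - 1, p_value = p,
                 rank_sums = setNames(R, colnames(matrix)),
                 alpha = alpha, significant = p < alpha),
            class = "zonedice_test")
}

#' @export
print.zonedice_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  cat(sprintf("  statistic %.5g on %d df, p = %.5g (%ssignificant at %g)\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  if (!is.null(x$pairwise)) {
    cat("  pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Conover post hoc test for unreplicated blocked data
#'
#' All pairwise method comparisons following a Friedman test on a complete
#' unreplicated block design. For methods i, j with within-block rank sums
#' `R_i`, `R_j`, the statistic
#' `t = |R_i - R_j| / sqrt( 2n(A1 - C1)/((n-1)(k-1)) * (1 - T2/(n(k-1))) )`
#' is referred to a t distribution on `(n-1)(k-1)` degrees of freedom, where
#' `A1`, `C1` and the tie-corrected Friedman statistic `T2` are as in
#' [friedman_test()]. Raw two-sided p-values are optionally adjusted with the
#' Benjamini-Hochberg step-up procedure. Identical columns give all pairwise
#' p = 1.
#'
#' @param matrix complete numeric matrix, blocks (patients) x methods.
#' @param adjust `"bh"` (Benjamini-Hochberg, default) or `"none"`.
#' @param alpha significance level (default 0.05).
#' @return object of class `zonedice_test` with the Friedman fields plus a
#'   `pairwise` `data.frame` (`method_a`, `method_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `significant`).
#' @export
conover_posthoc <- function(matrix, adjust = c("bh", "none"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  fr <- friedman_test(matrix, alpha = alpha)
  n <- nrow(matrix); k <- ncol(matrix)
  r <- block_ranks(matrix)
  R <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  T2 <- fr$statistic
  df <- (n - 1) * (k - 1)
  denom2 <- 2 * n * (A1 - C1) / df * (1 - T2 / (n * (k - 1)))
  pairs <- utils::combn(k, 2)
  method_names <- colnames(matrix)
  if (is.null(method_names)) method_names <- paste0("m", seq_len(k))
  stat <- p_raw <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    dif <- abs(R[i] - R[j])
    if (denom2 <= 0) {
      # degenerate: no within-block rank variance left (identical columns
      # give dif = 0 -> p = 1; perfect separation gives p -> 0)
      stat[c] <- if (dif == 0) 0 else Inf
    } else {
      stat[c] <- dif / sqrt(denom2)
    }
    p_raw[c] <- if (is.infinite(stat[c])) 0 else
      2 * pt(stat[c], df = df, lower.tail = FALSE)
    p_raw[c] <- min(p_raw[c], 1)
  }
  p_adj <- if (adjust == "bh") p.adjust(p_raw, method = "BH") else p_raw
  fr$method <- "Conover post hoc test for unreplicated blocked data"
  fr$pairwise <- data.frame(
    method_a = method_names[pairs[1, ]],
    method_b = method_names[pairs[2, ]],
    statistic = stat, p_raw = p_raw, p_adjusted = p_adj,
    significant = p_adj < alpha, stringsAsFactors = FALSE)
  fr
}
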