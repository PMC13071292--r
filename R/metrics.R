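#' Voxel overlap counts with a physical tolerance
#'
#' Computes the strict and tolerant confusion counts between a predicted and a
#' ground-truth mask on the same grid:
#' \itemize{
#'   \item `tp` — predicted voxels overlapping ground truth,
#'   \item `fp` — predicted voxels outside ground truth,
#'   \item `fn` — ground-truth voxels outside the prediction,
#'   \item `fp_tau` — predicted voxels outside the ground truth *dilated by
#'     the tolerance* (boundary-forgiven false positives),
#'   \item `fn_tau` — ground-truth voxels outside the *dilated prediction*.
#' }
#' Dilation is [dilate_physical()] at `tolerance` mm, so anisotropic spacing
#' is respected. All counts are voxel counts. At tolerance 0 the tolerant
#' counts equal the strict ones.
#'
#' @param pred,gt [binary_volume()] masks on identical grids.
#' @param tolerance non-negative physical margin in mm (default 5).
#' @return object of class `overlap_counts`: a list with the five counts plus
#'   `tolerance`.
#' @export
overlap_counts <- function(pred, gt, tolerance = 5) {
  bv_check_compatible(pred, gt)
  if (tolerance < 0) stop("`tolerance` must be >= 0")
  p <- pred$data; g <- gt$data
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(g & !p)
  if (tolerance == 0) {
    fp_tau <- fp; fn_tau <- fn
  } else {
    fp_tau <- sum(p & !dilate_physical(gt, tolerance)$data)
    fn_tau <- sum(g & !dilate_physical(pred, tolerance)$data)
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 fp_tau = fp_tau, fn_tau = fn_tau, tolerance = tolerance),
            class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat(sprintf(
    "<overlap_counts> tau=%g mm | TP %d FP %d FN %d FP_tau %d FN_tau %d\n",
    x$tolerance, x$tp, x$fp, x$fn, x$fp_tau, x$fn_tau))
  invisible(x)
}

#' Dice score coefficient and its tolerant variant
#'
#' `dsc()` is the classical volumetric Dice overlap
#' `2*TP / (2*TP + FP + FN)`. `dsc_tau()` replaces the strict false-positive
#' and false-negative counts with their tolerant versions,
#' `2*TP / (2*TP + FN_tau + FP_tau)`, forgiving boundary disagreement within
#' the tolerance while keeping TP strict: a prediction that merely hugs the
#' ground truth within the margin is not rewarded as overlap, but is no longer
#' punished as error.
#'
#' Both are `NA` (undefined) when both masks are empty. When TP is 0 but all
#' tolerant errors vanish (disjoint masks closer than the tolerance),
#' `dsc_tau()` is defined as 0: a complete miss stays a miss.
#'
#' @param counts an [overlap_counts()] object.
#' @return a value in `[0, 1]`, or `NA` when undefined.
#' @export
dsc <- function(counts) {
  stopifnot(inherits(counts, "overlap_counts"))
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(NA_real_)
  2 * counts$tp / den
}

#' @rdname dsc
#' @export
dsc_tau <- function(counts) {
  stopifnot(inherits(counts, "overlap_counts"))
  if (2 * counts$tp + counts$fp + counts$fn == 0) return(NA_real_)
  den <- 2 * counts$tp + counts$fn_tau + counts$fp_tau
  if (den == 0) return(0)
  2 * counts$tp / den
}

#' Per-patient metric record
#'
#' Evaluates one method's prediction for one patient. When the ground truth
#' contains a lesion, Dice and tolerant Dice are recorded; when it is empty,
#' both are undefined (`NA`) and the patient is instead flagged as a
#' *false-positive patient* if the method predicted any cancerous voxel.
#'
#' @param pred,gt [binary_volume()] masks on identical grids.
#' @param tolerance physical tolerance in mm (default 5).
#' @param patient_id,method_id identifiers carried into the record.
#' @return a one-row `data.frame` with columns `patient_id`, `method_id`,
#'   `has_gt_lesion`, `dsc`, `dsc_tau`, `tp`, `fp`, `fn`, `fp_tau`, `fn_tau`,
#'   `false_positive_patient`.
#' @export
evaluate_patient <- function(pred, gt, tolerance = 5,
                             patient_id = "patient", method_id = "method") {
  bv_check_compatible(pred, gt)
  has_gt <- any(gt$data)
  if (has_gt) {
    oc <- overlap_counts(pred, gt, tolerance)
    data.frame(patient_id = patient_id, method_id = method_id,
               has_gt_lesion = TRUE, dsc = dsc(oc), dsc_tau = dsc_tau(oc),
               tp = oc$tp, fp = oc$fp, fn = oc$fn,
               fp_tau = oc$fp_tau, fn_tau = oc$fn_tau,
               false_positive_patient = FALSE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = patient_id, method_id = method_id,
               has_gt_lesion = FALSE, dsc = NA_real_, dsc_tau = NA_real_,
               tp = 0L, fp = bv_count(pred), fn = 0L,
               fp_tau = NA_integer_, fn_tau = NA_integer_,
               false_positive_patient = any(pred$data),
               stringsAsFactors = FALSE)
  }
}
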