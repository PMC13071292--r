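#' Prostate zone pair
#'
#' Bundles the transition-zone (TZ) and peripheral-zone (PZ) masks of one
#' patient. Upstream zone segmentations are imperfect — gaps open between the
#' zones and the zones overlap — and [postprocess_zones()] repairs both
#' faults.
#'
#' @param tz,pz [binary_volume()] masks on identical grids.
#' @param processed has the pair been repaired (TZ and PZ then disjoint)?
#' @return an object of class `zone_pair`.
#' @export
zone_pair <- function(tz, pz, processed = FALSE) {
  bv_check_compatible(tz, pz)
  if (processed && any(tz$data & pz$data))
    stop("processed zone pair must have disjoint TZ and PZ")
  structure(list(tz = tz, pz = pz, processed = processed),
            class = "zone_pair")
}

#' @export
print.zone_pair <- function(x, ...) {
  cat(sprintf("<zone_pair> TZ %d vox, PZ %d vox, overlap %d vox%s\n",
              bv_count(x$tz), bv_count(x$pz),
              sum(x$tz$data & x$pz$data),
              if (x$processed) " [processed]" else ""))
  invisible(x)
}

#' Repair faulty TZ/PZ masks
#'
#' The peripheral zone is repaired as
#' `dilate(PZ) AND closing(PZ OR TZ) AND NOT TZ`:
#' the dilation fills small gaps toward TZ, the conjunction with the closing
#' of the zone union confines that filling to the space between the zones, and
#' removing TZ guarantees the repaired PZ avoids the raw TZ. The transition
#' zone is then `dilate(TZ) AND closing(PZ OR TZ) AND NOT f_PZ`, which fills
#' the remaining gaps and cedes any contested voxel to the already-repaired
#' PZ, so the output zones are disjoint by construction. Kernels are discrete
#' balls in voxel units: radius `dilate_r` (default 5) for the dilations and
#' `closing_r` (default 10) for the closing, the empirically chosen sizes for
#' isotropically resampled prostate grids.
#'
#' @param pz,tz raw zone masks ([binary_volume()]) on identical grids.
#' @param dilate_r dilation ball radius, voxels.
#' @param closing_r closing ball radius, voxels.
#' @return `postprocess_pz` / `postprocess_tz` return a [binary_volume()];
#'   `postprocess_zones` returns a processed [zone_pair()] computing the
#'   closing only once.
#' @name zone-postprocess
NULL

#' @rdname zone-postprocess
#' @export
postprocess_pz <- function(pz, tz, dilate_r = 5, closing_r = 10) {
  bv_check_compatible(pz, tz)
  cl <- closing_voxel(bv_or(pz, tz), closing_r)
  bv_diff(bv_and(dilate_voxel(pz, dilate_r), cl), tz)
}

#' @rdname zone-postprocess
#' @export
postprocess_tz <- function(pz, tz, dilate_r = 5, closing_r = 10) {
  bv_check_compatible(pz, tz)
  cl <- closing_voxel(bv_or(pz, tz), closing_r)
  fpz <- bv_diff(bv_and(dilate_voxel(pz, dilate_r), cl), tz)
  bv_diff(bv_and(dilate_voxel(tz, dilate_r), cl), fpz)
}

#' @rdname zone-postprocess
#' @export
postprocess_zones <- function(pz, tz, dilate_r = 5, closing_r = 10) {
  bv_check_compatible(pz, tz)
  cl <- closing_voxel(bv_or(pz, tz), closing_r)
  fpz <- bv_diff(bv_and(dilate_voxel(pz, dilate_r), cl), tz)
  ftz <- bv_diff(bv_and(dilate_voxel(tz, dilate_r), cl), fpz)
  zone_pair(tz = ftz, pz = fpz, processed = TRUE)
}

#' Refine a zone mask against the prostate gland mask
#'
#' Post-processed zones can spill outside the gland; refinement intersects the
#' zone with the prostate mask. In the upstream workflow the refined masks
#' feed model training while unrefined ones are used for evaluation, so both
#' forms are kept available.
#'
#' @param zone,prostate [binary_volume()] masks on identical grids.
#' @return a [binary_volume()].
#' @export
refine_with_prostate <- function(zone, prostate) {
  bv_and(zone, prostate)
}

#' Whole-prostate mask from a zone pair
#'
#' The whole-gland mask used by the evaluation is the disjunction of the TZ
#' and PZ masks.
#'
#' @param pair a [zone_pair()].
#' @return a [binary_volume()].
#' @export
whole_prostate_from_zones <- function(pair) {
  stopifnot(inherits(pair, "zone_pair"))
  bv_or(pair$tz, pair$pz)
}
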