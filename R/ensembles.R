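#' Zone-restricted input masking
#'
#' Zeroes every voxel of a scalar image (e.g. a T2/ADC/DWI channel) outside a
#' region mask; inside, values pass through unchanged. This is how
#' zone-specific segmentation models receive zone-restricted inputs.
#'
#' @param image numeric 3-D array.
#' @param region a [binary_volume()] with the image's shape.
#' @return numeric array of the image's shape.
#' @export
apply_region_mask <- function(image, region) {
  stopifnot(is_binary_volume(region))
  if (!identical(dim(image), dim(region$data)))
    stop("grid mismatch between image and region")
  image * as.numeric(region$data)
}

#' Ensemble specification
#'
#' The compared combination schemes are disjunctions of member model outputs.
#' Member model identifiers name the zone a model segments and the imaging
#' sequences it sees: `tz_t2` (TZ model on T2 only), `pz_adc_dwi` (PZ model on
#' ADC+DWI), `tz_all` / `pz_all` (zone models on all three sequences) and
#' `prostate_all_zones` (whole-gland model on all sequences plus zone
#' channels — the baseline). Built-in schemes:
#' \itemize{
#'   \item `ensemble1` = `tz_t2 | pz_adc_dwi`
#'   \item `ensemble2` = `tz_all | pz_all`
#'   \item `ensemble3` = `tz_all | pz_all | prostate_all_zones`
#'   \item `ensemble4` = `pz_all | prostate_all_zones`
#'   \item `baseline`  = `prostate_all_zones`
#' }
#'
#' @param name one of the built-in scheme names above, or any label when
#'   `members` is given explicitly.
#' @param members character vector of member method ids (>= 1); defaults to
#'   the built-in member set for `name`.
#' @return object of class `ensemble_spec` with fields `name`, `members`.
#' @export
ensemble_spec <- function(name, members = NULL) {
  if (is.null(members)) {
    members <- switch(name,
      ensemble1 = c("tz_t2", "pz_adc_dwi"),
      ensemble2 = c("tz_all", "pz_all"),
      ensemble3 = c("tz_all", "pz_all", "prostate_all_zones"),
      ensemble4 = c("pz_all", "prostate_all_zones"),
      baseline  = "prostate_all_zones",
      stop("unknown built-in ensemble: ", name))
  }
  if (length(members) < 1) stop("an ensemble needs at least one member")
  structure(list(name = name, members = as.character(members)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> %s = %s\n", x$name,
              paste(x$members, collapse = " | ")))
  invisible(x)
}

#' Names of the built-in combination schemes
#' @return character vector.
#' @export
builtin_ensembles <- function() {
  c("baseline", "ensemble1", "ensemble2", "ensemble3", "ensemble4")
}

#' Combine member predictions by disjunction
#'
#' Voxelwise logical OR of all member predictions: a voxel is cancerous in the
#' ensemble output when any member marks it. `predictions` is a named list of
#' [binary_volume()] masks keyed by member method id; members listed in the
#' spec are looked up by name. Optionally each member can be hard-clipped to a
#' zone mask before combination (`clip = list(member_id = zone_volume)`),
#' since zone-masked inputs do not guarantee zone-bounded outputs; default is
#' no clipping.
#'
#' @param predictions named list of [binary_volume()] masks.
#' @param spec an [ensemble_spec()] (or built-in scheme name).
#' @param clip optional named list of zone masks to intersect members with.
#' @return a [binary_volume()].
#' @export
combine_predictions <- function(predictions, spec, clip = NULL) {
  if (is.character(spec)) spec <- ensemble_spec(spec)
  stopifnot(inherits(spec, "ensemble_spec"))
  missing <- setdiff(spec$members, names(predictions))
  if (length(missing))
    stop("missing member prediction(s): ", paste(missing, collapse = ", "))
  vols <- predictions[spec$members]
  if (!is.null(clip))
    for (m in intersect(names(clip), spec$members))
      vols[[m]] <- bv_and(vols[[m]], clip[[m]])
  Reduce(bv_or, vols)
}

#' Majority-vote combiner (extension)
#'
#' Alternative to disjunction: a voxel is foreground when more than half of
#' the members mark it. Kept as an explicitly labelled extension for
#' false-positive-accumulation experiments; the evaluated schemes all use
#' disjunction.
#'
#' @inheritParams combine_predictions
#' @return a [binary_volume()].
#' @export
combine_majority <- function(predictions, spec) {
  if (is.character(spec)) spec <- ensemble_spec(spec)
  vols <- predictions[spec$members]
  stopifnot(length(vols) >= 1, !anyNA(names(vols)))
  acc <- Reduce(`+`, lapply(vols, function(v) array(as.integer(v$data),
                                                    dim = dim(v$data))))
  bv_like(vols[[1]], acc > length(vols) / 2)
}
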