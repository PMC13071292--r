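#' Labelled biopsy set
#'
#' Biopsies for one patient as a labelled volume (one positive label per
#' biopsy mask) plus one diagnostic outcome per label: `benign`,
#' `undetermined` or `malignant`. Only malignant biopsies can confirm a
#' delineated lesion.
#'
#' @param labels integer 3-D array of biopsy labels (0 = background).
#' @param outcomes character vector, one outcome per label `1..max(labels)`.
#' @param spacing voxel spacing in mm, as in [binary_volume()].
#' @return an object of class `biopsy_set`.
#' @export
biopsy_set <- function(labels, outcomes, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  outcomes <- as.character(outcomes)
  if (length(outcomes) != n)
    stop("need exactly one outcome per biopsy label (", n, ")")
  bad <- setdiff(unique(outcomes), c("benign", "undetermined", "malignant"))
  if (length(bad))
    stop("unknown biopsy outcome(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels, outcomes = outcomes,
                 spacing = as.numeric(spacing)),
            class = "biopsy_set")
}

#' @export
print.biopsy_set <- function(x, ...) {
  cat(sprintf("<biopsy_set> %d biopsies (%d malignant, %d benign, %d undetermined)\n",
              length(x$outcomes), sum(x$outcomes == "malignant"),
              sum(x$outcomes == "benign"), sum(x$outcomes == "undetermined")))
  invisible(x)
}

#' Mask of all malignant biopsy voxels
#'
#' @param biopsies a [biopsy_set()].
#' @return a [binary_volume()].
#' @export
malignant_mask <- function(biopsies) {
  stopifnot(inherits(biopsies, "biopsy_set"))
  mal <- which(biopsies$outcomes == "malignant")
  binary_volume(array(biopsies$labels %in% mal, dim = dim(biopsies$labels)),
                spacing = biopsies$spacing)
}

#' Biopsy-confirmed ground truth
#'
#' The evaluation ground truth is the set of manually delineated lesions
#' (connected components of the manual mask) confirmed by a malignant biopsy.
#' A lesion is confirmed when it either
#' \enumerate{
#'   \item intersects a malignant biopsy mask, or
#'   \item has a malignant biopsy voxel within `radius` mm of its nearest
#'     voxel (surface distance, voxel centre to voxel centre, inclusive).
#' }
#' The 5 mm default encodes the pitch of the standard biopsy grid, whose
#' evenly spaced holes can displace a sample by up to that much. Benign and
#' undetermined biopsies never confirm. Setting `radius = 0` reduces
#' confirmation to pure intersection.
#'
#' The returned object also flags the cohort-construction inconsistency used
#' for patient exclusion: a case is `inconsistent` when at least one
#' delineated lesion stays unconfirmed although the patient has malignant
#' biopsies elsewhere. Exclusion itself is left to the caller.
#'
#' @param manual manual delineation mask ([binary_volume()]).
#' @param biopsies a [biopsy_set()] on the same grid.
#' @param radius confirmation radius in mm (default 5).
#' @param connectivity component connectivity (default 26).
#' @return object of class `confirmed_ground_truth`: list with `lesions` (a
#'   [connected_components()] map of confirmed lesions, relabelled 1..k),
#'   `mask` (their union as a [binary_volume()]), `table` (per input component:
#'   label, confirmation rule `intersect`/`within-radius`/`none`, voxels,
#'   volume mm^3), `radius`, `inconsistent`.
#' @export
confirm_lesions <- function(manual, biopsies, radius = 5, connectivity = 26) {
  stopifnot(is_binary_volume(manual), inherits(biopsies, "biopsy_set"))
  if (!identical(dim(manual$data), dim(biopsies$labels)))
    stop("grid mismatch between manual mask and biopsies")
  if (radius < 0) stop("`radius` must be >= 0")
  comps <- connected_components(manual, connectivity)
  mal <- malignant_mask(biopsies)
  mal$spacing <- manual$spacing  # biopsies share the case grid
  any_mal <- any(mal$data)
  d2 <- if (any_mal && radius > 0) distance_transform(mal, squared = TRUE)
        else NULL
  rule <- character(comps$n)
  for (l in seq_len(comps$n)) {
    inside <- comps$labels == l
    if (any_mal && any(mal$data[inside])) {
      rule[l] <- "intersect"
    } else if (!is.null(d2) && any(d2[inside] <= radius^2)) {
      rule[l] <- "within-radius"
    } else {
      rule[l] <- "none"
    }
  }
  keep <- which(rule != "none")
  new_labels <- array(0L, dim = dim(comps$labels))
  for (i in seq_along(keep)) new_labels[comps$labels == keep[i]] <- i
  lesions <- lesion_map_from_labels(new_labels, manual$spacing, connectivity)
  structure(list(
    lesions = lesions,
    mask = binary_volume(new_labels > 0L, spacing = manual$spacing,
                         affine = manual$affine),
    table = data.frame(label = seq_len(comps$n), rule = rule,
                       voxels = comps$voxel_counts,
                       volume_mm3 = comps$volumes_mm3,
                       confirmed = rule != "none",
                       stringsAsFactors = FALSE),
    radius = radius,
    inconsistent = any_mal && any(rule == "none")
  ), class = "confirmed_ground_truth")
}

#' @export
print.confirmed_ground_truth <- function(x, ...) {
  cat(sprintf("<confirmed_ground_truth> %d of %d delineated lesion(s) confirmed (radius %g mm)%s\n",
              x$lesions$n, nrow(x$table), x$radius,
              if (x$inconsistent) " [inconsistent case]" else ""))
  invisible(x)
}

#' Assign lesions to prostate zones
#'
#' Labels each lesion with the zone(s) it overlaps; the zone holding the
#' majority of the lesion's voxels is reported as primary. Exact ties break
#' toward PZ (the zone with the higher prior lesion prevalence); lesions
#' overlapping neither zone get primary `"none"` with a warning.
#'
#' @param lesions a `lesion_map`.
#' @param zones a [zone_pair()] on the same grid.
#' @return `data.frame` with columns `label`, `tz_voxels`, `pz_voxels`,
#'   `primary` (`"TZ"`, `"PZ"` or `"none"`).
#' @export
assign_lesion_zones <- function(lesions, zones) {
  stopifnot(inherits(lesions, "lesion_map"), inherits(zones, "zone_pair"))
  if (!identical(dim(lesions$labels), dim(zones$tz$data)))
    stop("grid mismatch between lesions and zones")
  out <- data.frame(label = seq_len(lesions$n),
                    tz_voxels = integer(lesions$n),
                    pz_voxels = integer(lesions$n),
                    primary = character(lesions$n),
                    stringsAsFactors = FALSE)
  for (l in seq_len(lesions$n)) {
    inside <- lesions$labels == l
    ntz <- sum(zones$tz$data[inside])
    npz <- sum(zones$pz$data[inside])
    out$tz_voxels[l] <- ntz
    out$pz_voxels[l] <- npz
    out$primary[l] <- if (ntz == 0 && npz == 0) "none"
                      else if (ntz > npz) "TZ" else "PZ"
  }
  if (any(out$primary == "none") && lesions$n > 0)
    warning("lesion(s) outside both zones: ",
            paste(out$label[out$primary == "none"], collapse = ", "))
  out
}

#' Lesion size summary
#'
#' Minimum, maximum, mean and median lesion volume in cubic millimetres.
#'
#' @param lesions a `lesion_map`.
#' @return named list `n`, `min`, `max`, `mean`, `median` (`NA` when empty).
#' @export
lesion_size_stats <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_map"))
  v <- lesions$volumes_mm3
  if (length(v) == 0)
    return(list(n = 0L, min = NA_real_, max = NA_real_,
                mean = NA_real_, median = NA_real_))
  list(n = length(v), min = min(v), max = max(v),
       mean = mean(v), median = median(v))
}
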