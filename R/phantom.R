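#' Synthetic prostate phantom configuration
#'
#' Parameters of the seedable phantom cohort that stands in for a clinical
#' dataset: an ellipsoidal gland partitioned into an inner transition zone
#' (TZ) and a peripheral-zone (PZ) shell with injectable segmentation faults
#' (a gap of `gap_width_mm` between the zones in the superior half, an
#' overlap of `overlap_width_mm` in the inferior half; both 0 gives an exact
#' partition), 0-2 blob lesions per patient with a configurable TZ/PZ
#' imbalance, biopsy points on a 5 mm grid labelled malignant inside
#' designated lesions, and per-method degraded copies of the truth serving as
#' "predictions".
#'
#' Cohort composition defaults mirror a 119-patient study population: 77
#' lesion-free patients and 42 lesion-bearing (36 with one lesion, 6 with
#' two), with roughly 20% of lesions in TZ. Spacing defaults to the
#' anisotropic acquisition geometry (0.5 x 0.5 mm in-slice, 2.5 mm between
#' slices).
#'
#' @param shape grid shape in voxels.
#' @param spacing voxel spacing in mm.
#' @param n_cases cohort size.
#' @param n_lesion_free number of patients with empty ground truth.
#' @param two_lesion_frac fraction of lesion-bearing patients with 2 lesions.
#' @param tz_lesion_prob probability a lesion is placed in TZ.
#' @param lesion_volume_mm3 length-2 range of lesion volumes.
#' @param decoy_prob probability a lesion-bearing case carries one extra
#'   unconfirmed (decoy) delineation.
#' @param decoy_margin_mm minimum distance from a decoy to any confirmed
#'   lesion (must exceed the confirmation radius).
#' @param gap_width_mm,overlap_width_mm zone-fault widths in mm.
#' @param biopsy_pitch_mm in-plane biopsy grid pitch.
#' @param biopsy_slice_step grid nodes every this many slices.
#' @param n_biopsies_target expected biopsies per patient.
#' @param undetermined_prob probability a non-malignant biopsy is
#'   "undetermined" rather than "benign".
#' @param methods named list of per-method degradation settings, each a list
#'   with `zone` (`"TZ"`, `"PZ"` or `NULL` for whole gland), `jitter_mm`,
#'   `drop_p`, `spurious_rate` (expected spurious blobs per case).
#' @param max_spurious_sites number of shared candidate spurious-blob sites
#'   per case (shared across methods so ensemble unions stay well-formed).
#' @param seed base seed; each case derives its own stream from
#'   `(seed, case_index)`.
#' @return object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(shape = c(96, 96, 20),
                           spacing = c(0.5, 0.5, 2.5),
                           n_cases = 119,
                           n_lesion_free = 77,
                           two_lesion_frac = 6 / 42,
                           tz_lesion_prob = 0.2,
                           lesion_volume_mm3 = c(250, 4000),
                           decoy_prob = 0.25,
                           decoy_margin_mm = 8,
                           gap_width_mm = 2,
                           overlap_width_mm = 2,
                           biopsy_pitch_mm = 5,
                           biopsy_slice_step = 2,
                           n_biopsies_target = 15,
                           undetermined_prob = 0.1,
                           methods = default_phantom_methods(),
                           max_spurious_sites = 6,
                           seed = 1) {
  cfg <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
              n_cases = as.integer(n_cases),
              n_lesion_free = as.integer(n_lesion_free),
              two_lesion_frac = two_lesion_frac,
              tz_lesion_prob = tz_lesion_prob,
              lesion_volume_mm3 = lesion_volume_mm3,
              decoy_prob = decoy_prob, decoy_margin_mm = decoy_margin_mm,
              gap_width_mm = gap_width_mm,
              overlap_width_mm = overlap_width_mm,
              biopsy_pitch_mm = biopsy_pitch_mm,
              biopsy_slice_step = as.integer(biopsy_slice_step),
              n_biopsies_target = n_biopsies_target,
              undetermined_prob = undetermined_prob,
              methods = methods,
              max_spurious_sites = as.integer(max_spurious_sites),
              seed = as.integer(seed))
  stopifnot(length(cfg$shape) == 3, all(cfg$shape > 0),
            length(cfg$spacing) == 3, all(cfg$spacing > 0),
            cfg$n_cases >= 1, cfg$n_lesion_free >= 0,
            cfg$n_lesion_free <= cfg$n_cases,
            cfg$two_lesion_frac >= 0, cfg$two_lesion_frac <= 1,
            cfg$tz_lesion_prob >= 0, cfg$tz_lesion_prob <= 1,
            length(cfg$lesion_volume_mm3) == 2,
            all(cfg$lesion_volume_mm3 > 0),
            cfg$decoy_prob >= 0, cfg$decoy_prob <= 1,
            cfg$gap_width_mm >= 0, cfg$overlap_width_mm >= 0,
            cfg$biopsy_pitch_mm > 0, cfg$biopsy_slice_step >= 1,
            cfg$undetermined_prob >= 0, cfg$undetermined_prob <= 1,
            length(cfg$methods) >= 1)
  class(cfg) <- "phantom_config"
  cfg
}

#' Default degradation profiles of the five simulated segmentation methods
#'
#' Zone-specific models only produce lesions whose designated zone matches;
#' the whole-gland baseline sees everything but drops more lesions and emits
#' fewer spurious foci, mimicking an under-detecting but specific model.
#'
#' @return named list of per-method settings (see [phantom_config()]).
#' @export
default_phantom_methods <- function() {
  list(
    tz_t2              = list(zone = "TZ", jitter_mm = 2.0, drop_p = 0.30,
                              spurious_rate = 0.30),
    pz_adc_dwi         = list(zone = "PZ", jitter_mm = 2.0, drop_p = 0.25,
                              spurious_rate = 0.30),
    tz_all             = list(zone = "TZ", jitter_mm = 1.5, drop_p = 0.20,
                              spurious_rate = 0.35),
    pz_all             = list(zone = "PZ", jitter_mm = 1.5, drop_p = 0.15,
                              spurious_rate = 0.35),
    prostate_all_zones = list(zone = NULL, jitter_mm = 1.5, drop_p = 0.30,
                              spurious_rate = 0.15)
  )
}

# physical voxel-centre coordinate vectors (mm) per axis
phys_axes <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

# ellipsoid indicator on the grid: centre and semi-axes in mm
ellipsoid_mask <- function(ax, centre, semi) {
  qx <- ((ax$x - centre[1]) / semi[1])^2
  qy <- ((ax$y - centre[2]) / semi[2])^2
  qz <- ((ax$z - centre[3]) / semi[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

# solid ball (physical mm) indicator
ball_mask <- function(ax, centre, radius) {
  qx <- (ax$x - centre[1])^2
  qy <- (ax$y - centre[2])^2
  qz <- (ax$z - centre[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= radius^2
}

# lesion-count profile per case index: deterministic cohort composition
case_profile <- function(config, case_index) {
  n_pos <- config$n_cases - config$n_lesion_free
  n_two <- round(n_pos * config$two_lesion_frac)
  if (case_index <= config$n_lesion_free) 0L
  else if (case_index <= config$n_cases - n_two) 1L
  else 2L
}

# random blob: main ball plus 1-2 satellite balls, all inside `allowed`
place_blob <- function(ax, centre, radius, spacing) {
  blob <- ball_mask(ax, centre, radius)
  for (s in seq_len(1 + rbinom(1, 1, 0.5))) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    off <- centre + dir * radius * runif(1, 0.3, 0.6) * c(1, 1, 0.4)
    blob <- blob | ball_mask(ax, off, radius * runif(1, 0.5, 0.7))
  }
  blob
}

#' Generate one synthetic patient case
#'
#' Deterministic given `(config$seed, case_index)`. Returns the full bundle a
#' patient contributes to the pipeline: faulty raw zone masks, the gland
#' mask, the manual delineation (true lesions plus optional unconfirmed
#' decoy), the planted ground truth with per-lesion zone labels, the biopsy
#' set, and one degraded prediction per configured method.
#'
#' Generator guarantees used by downstream recovery tests: every designated
#' (true) lesion contains at least one malignant biopsy voxel; decoy
#' delineations keep at least `decoy_margin_mm` from malignant biopsies;
#' per-method dropped lesions and planted spurious blobs are recorded in
#' `meta`; spurious blobs are drawn from a per-case pool of well-separated
#' candidate sites shared across methods, so disjunctions of method outputs
#' never merge a spurious focus into a true-lesion component.
#'
#' @param config a [phantom_config()].
#' @param case_index 1-based case number.
#' @return object of class `patient_case`: list with `patient_id`, `prostate`,
#'   `tz_raw`, `pz_raw`, `manual`, `gt`, `gt_lesions`, `biopsies`,
#'   `predictions` (named list), `meta`.
#' @export
generate_case <- function(config, case_index) {
  stopifnot(inherits(config, "phantom_config"),
            case_index >= 1, case_index <= config$n_cases)
  with_seed(mix_seed(config$seed, case_index), {
    shp <- config$shape; sp <- config$spacing
    ax <- phys_axes(shp, sp)
    fov <- shp * sp
    centre <- fov / 2 + runif(3, -1.5, 1.5)
    gland_semi <- pmin(c(18, 15, 14) * runif(3, 0.9, 1.1), fov / 2 - 2)
    prostate <- binary_volume(ellipsoid_mask(ax, centre, gland_semi), sp)
    tz_semi <- gland_semi * runif(1, 0.5, 0.6)
    tz <- ellipsoid_mask(ax, centre, tz_semi)

    # faulty PZ: shell of the gland around an inner exclusion whose size
    # differs between the superior (gap) and inferior (overlap) halves
    zmid <- centre[3]
    upper <- outer(outer(rep(0, shp[1]), rep(0, shp[2]), `+`),
                   as.numeric(ax$z > zmid), `+`) > 0
    excl_gap <- ellipsoid_mask(ax, centre, tz_semi + config$gap_width_mm)
    excl_ovl <- ellipsoid_mask(ax, centre,
                               pmax(tz_semi - config$overlap_width_mm, 0.5))
    pz <- prostate$data & !((excl_gap & upper) | (excl_ovl & !upper))
    tz_raw <- binary_volume(tz, sp)
    pz_raw <- binary_volume(pz, sp)

    # lesions
    n_lesions <- case_profile(config, case_index)
    gt_arr <- array(FALSE, shp)
    lesion_zone <- character(0)
    lesion_masks <- list()
    centres <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    vol_rng <- config$lesion_volume_mm3
    for (l in seq_len(n_lesions)) {
      zone <- if (runif(1) < config$tz_lesion_prob) "TZ" else "PZ"
      target <- runif(1, vol_rng[1], vol_rng[2])
      radius <- (3 * target / (4 * pi))^(1 / 3)
      # lesions must stay separate connected components: exclude everything
      # adjacent (26-neighbourhood) to already-placed lesions
      gt_excl <- if (any(gt_arr))
        dilate_voxel(binary_volume(gt_arr, sp), 1)$data
      else gt_arr
      placed <- FALSE
      r_try <- radius
      for (try in 1:120) {
        # a large lesion may not fit the thin PZ shell of a small gland:
        # shrink the target every few failed attempts, and as a last resort
        # re-draw the zone
        if (try %% 8 == 0) r_try <- max(r_try * 0.75, 2.5)
        if (try %% 40 == 0) zone <- if (zone == "TZ") "PZ" else "TZ"
        zone_arr <- if (zone == "TZ") tz else (prostate$data & !tz)
        host <- zone_arr & !gt_excl
        if (!any(host)) next
        v <- sample(which(host), 1)
        idx <- arrayInd(v, shp)
        c_mm <- (idx - 1) * sp
        # early attempts keep realistic inter-lesion distance; later ones
        # only require disjoint components
        if (try <= 30 && nrow(centres) > 0 &&
            any(sqrt(colSums((t(centres) - as.numeric(c_mm))^2)) <
                radii + r_try + 3))
          next
        blob <- place_blob(ax, as.numeric(c_mm), r_try, sp) & prostate$data
        if (sum(blob) < 8 || any(blob & gt_excl)) next
        # keep the designated zone the majority zone
        if (sum(blob & zone_arr) <= sum(blob) / 2) next
        gt_arr <- gt_arr | blob
        lesion_masks[[l]] <- blob
        lesion_zone <- c(lesion_zone, zone)
        centres <- rbind(centres, as.numeric(c_mm))
        radii <- c(radii, r_try)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place lesion ", l, " of case ", case_index,
             " within its zone after bounded retries")
    }
    gt <- binary_volume(gt_arr, sp)
    gt_lesions <- connected_components(gt, 26)
    # reorder per-lesion bookkeeping from placement order to component-label
    # (scan) order so meta indices match gt_lesions labels
    if (n_lesions > 0) {
      comp_of <- vapply(lesion_masks,
                        function(b) gt_lesions$labels[which(b)[1]],
                        integer(1))
      lesion_masks[comp_of] <- lesion_masks
      lesion_zone[comp_of] <- lesion_zone
      radii[comp_of] <- radii
    }

    # optional decoy delineation, kept away from all true lesions
    manual_arr <- gt_arr
    has_decoy <- FALSE
    if (n_lesions > 0 && runif(1) < config$decoy_prob) {
      d_gt <- if (any(gt_arr)) distance_transform(gt, squared = FALSE) else NULL
      r_dec <- (3 * runif(1, vol_rng[1], vol_rng[1] * 2) / (4 * pi))^(1 / 3)
      inside <- prostate$data & (d_gt > config$decoy_margin_mm + r_dec + 2)
      cand <- which(inside)
      if (length(cand) > 0) {
        for (try in 1:25) {
          v <- sample(cand, 1)
          c_mm <- (arrayInd(v, shp) - 1) * sp
          blob <- ball_mask(ax, as.numeric(c_mm), r_dec) & prostate$data
          if (sum(blob) < 8) next
          if (any(d_gt[blob] <= config$decoy_margin_mm)) next
          manual_arr <- manual_arr | blob
          has_decoy <- TRUE
          break
        }
      }
    }
    manual <- binary_volume(manual_arr, sp)

    # biopsy grid: 5 mm pitch in-plane, every `biopsy_slice_step` slices,
    # jittered origin, trimmed to the gland, thinned toward the target count;
    # nodes inside true lesions are malignant and always kept
    pitch <- config$biopsy_pitch_mm
    gx <- seq(runif(1, 0, pitch), fov[1], by = pitch)
    gy <- seq(runif(1, 0, pitch), fov[2], by = pitch)
    gz <- ax$z[seq(sample(config$biopsy_slice_step, 1), shp[3],
                   by = config$biopsy_slice_step)]
    nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    vi <- cbind(round(nodes[, 1] / sp[1]) + 1,
                round(nodes[, 2] / sp[2]) + 1,
                round(nodes[, 3] / sp[3]) + 1)
    ok <- vi[, 1] >= 1 & vi[, 1] <= shp[1] &
          vi[, 2] >= 1 & vi[, 2] <= shp[2] &
          vi[, 3] >= 1 & vi[, 3] <= shp[3]
    vi <- vi[ok, , drop = FALSE]
    in_gland <- prostate$data[vi]
    vi <- vi[in_gland, , drop = FALSE]
    vi <- vi[!duplicated(vi), , drop = FALSE]
    in_lesion <- gt_arr[vi]
    keep <- which(in_lesion)
    others <- which(!in_lesion)
    n_more <- max(config$n_biopsies_target - length(keep), 3)
    if (length(others) > n_more)
      others <- sample(others, n_more)
    vi <- vi[c(keep, others), , drop = FALSE]
    # guarantee every true lesion holds a malignant biopsy: add its densest
    # voxel when the grid missed it
    for (l in seq_len(gt_lesions$n)) {
      inside <- gt_lesions$labels == l
      hit <- any(inside[vi])
      if (!hit) {
        d_in <- distance_transform(
          binary_volume(!inside, sp), squared = TRUE)
        v <- which(inside)[which.max(d_in[inside])]
        vi <- rbind(vi, arrayInd(v, shp))
      }
    }
    labels <- array(0L, shp)
    outcomes <- character(nrow(vi))
    for (b in seq_len(nrow(vi))) {
      labels[vi[b, 1], vi[b, 2], vi[b, 3]] <- b
      outcomes[b] <- if (gt_arr[vi[b, 1], vi[b, 2], vi[b, 3]]) "malignant"
                     else if (runif(1) < config$undetermined_prob) "undetermined"
                     else "benign"
    }
    biopsies <- biopsy_set(labels, outcomes, spacing = sp)

    # shared pool of spurious-blob sites, pairwise separated and away from
    # every delineation
    sites <- list()
    if (config$max_spurious_sites > 0) {
      d_man <- if (any(manual_arr))
        distance_transform(manual, squared = FALSE) else NULL
      site_centres <- matrix(numeric(0), ncol = 3)
      for (s in seq_len(config$max_spurious_sites)) {
        r_s <- runif(1, 2, 4)
        for (try in 1:20) {
          v <- sample(which(prostate$data), 1)
          c_mm <- as.numeric((arrayInd(v, shp) - 1) * sp)
          if (!is.null(d_man) &&
              d_man[matrix(arrayInd(v, shp), 1)] <= 6 + r_s) next
          if (nrow(site_centres) > 0 &&
              any(sqrt(colSums((t(site_centres) - c_mm)^2)) < 2 * 4 + 3))
            next
          blob <- ball_mask(ax, c_mm, r_s)
          if (!any(blob)) next
          sites[[length(sites) + 1]] <- blob
          site_centres <- rbind(site_centres, c_mm)
          break
        }
      }
    }

    # per-method degraded predictions
    predictions <- list()
    meta_methods <- list()
    for (m in names(config$methods)) {
      mm <- config$methods[[m]]
      eligible <- if (is.null(mm$zone)) seq_len(gt_lesions$n)
                  else which(lesion_zone == mm$zone)
      pred_arr <- array(FALSE, shp)
      dropped <- integer(0)
      out_of_zone <- setdiff(seq_len(gt_lesions$n), eligible)
      for (l in eligible) {
        if (runif(1) < mm$drop_p) { dropped <- c(dropped, l); next }
        lesion <- binary_volume(lesion_masks[[l]], sp)
        delta <- runif(1, 0.5, 1) * mm$jitter_mm * sample(c(-1, 1), 1)
        warped <- if (delta >= 0) dilate_physical(lesion, delta)
                  else erode_physical(lesion, -delta)
        if (!any(warped$data)) warped <- erode_physical(lesion, radii[l] / 2)
        if (!any(warped$data)) warped <- lesion
        pred_arr <- pred_arr | warped$data
      }
      used_sites <- integer(0)
      if (length(sites) > 0 && mm$spurious_rate > 0) {
        p_site <- min(mm$spurious_rate / length(sites), 1)
        for (s in seq_along(sites))
          if (runif(1) < p_site) {
            pred_arr <- pred_arr | sites[[s]]
            used_sites <- c(used_sites, s)
          }
      }
      predictions[[m]] <- binary_volume(pred_arr, sp)
      meta_methods[[m]] <- list(dropped = dropped,
                                out_of_zone = out_of_zone,
                                spurious_sites = used_sites)
    }

    structure(list(
      patient_id = sprintf("case%03d", case_index),
      prostate = prostate, tz_raw = tz_raw, pz_raw = pz_raw,
      manual = manual, gt = gt, gt_lesions = gt_lesions,
      biopsies = biopsies, predictions = predictions,
      meta = list(n_lesions = n_lesions, lesion_zone = lesion_zone,
                  has_decoy = has_decoy, methods = meta_methods,
                  n_spurious_sites = length(sites))
    ), class = "patient_case")
  })
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %d lesion(s)%s, %d biopsies, %d prediction(s)\n",
              x$patient_id, x$meta$n_lesions,
              if (x$meta$has_decoy) " + decoy" else "",
              length(x$biopsies$outcomes), length(x$predictions)))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' @param config a [phantom_config()].
#' @param indices which cases to generate (default all).
#' @return list of [generate_case()] results.
#' @export
generate_cohort <- function(config, indices = seq_len(config$n_cases)) {
  lapply(indices, function(i) generate_case(config, i))
}

#' Degrade a mask into a synthetic prediction
#'
#' Standalone controlled-error operator for metric experiments: each
#' connected component of `mask` is independently dilated or eroded by a
#' random physical margin up to `jitter_mm` (magnitude drawn between half and
#' all of it, sign random), dropped entirely with probability `drop_p`, and a
#' Poisson(`spurious_rate`) number of spurious balls is planted outside the
#' (slightly padded) mask — inside `region` when given. Deterministic per
#' seed. With all three parameters 0 the mask passes through unchanged.
#'
#' @param mask a [binary_volume()].
#' @param jitter_mm maximum boundary jitter in mm.
#' @param drop_p per-component drop probability.
#' @param spurious_rate expected number of spurious blobs.
#' @param seed integer seed.
#' @param region optional [binary_volume()] restricting spurious placement.
#' @param connectivity component connectivity (default 26).
#' @return a [binary_volume()]; attribute `degrade_meta` records `dropped`
#'   component labels and `n_spurious` planted blobs.
#' @export
degrade_mask <- function(mask, jitter_mm = 0, drop_p = 0, spurious_rate = 0,
                         seed = 1, region = NULL, connectivity = 26) {
  stopifnot(is_binary_volume(mask), jitter_mm >= 0,
            drop_p >= 0, drop_p <= 1, spurious_rate >= 0)
  if (jitter_mm == 0 && drop_p == 0 && spurious_rate == 0) return(mask)
  with_seed(as.integer(seed), {
    shp <- dim(mask$data); sp <- mask$spacing
    ax <- phys_axes(shp, sp)
    comps <- connected_components(mask, connectivity)
    out <- array(FALSE, shp)
    dropped <- integer(0)
    for (l in seq_len(comps$n)) {
      if (drop_p > 0 && runif(1) < drop_p) { dropped <- c(dropped, l); next }
      lesion <- lesion_mask(comps, l)
      if (jitter_mm > 0) {
        delta <- runif(1, 0.5, 1) * jitter_mm * sample(c(-1, 1), 1)
        warped <- if (delta >= 0) dilate_physical(lesion, delta)
                  else erode_physical(lesion, -delta)
        # boundary jitter never deletes a component (that is drop_p's job)
        if (any(warped$data)) lesion <- warped
      }
      out <- out | lesion$data
    }
    n_spur <- if (spurious_rate > 0) rpois(1, spurious_rate) else 0L
    planted <- 0L
    if (n_spur > 0) {
      # keep blobs clear of the (jittered) truth and of each other so every
      # planted blob is its own spurious component
      allowed <- !dilate_physical(mask, max(6, jitter_mm + 2))$data
      if (!is.null(region)) allowed <- allowed & region$data
      cand <- which(allowed)
      centres_used <- matrix(numeric(0), ncol = 3)
      for (s in seq_len(n_spur)) {
        if (length(cand) == 0) break
        for (try in 1:30) {
          r_s <- runif(1, 2, 4)
          v <- sample(cand, 1)
          c_mm <- as.numeric((arrayInd(v, shp) - 1) * sp)
          if (nrow(centres_used) > 0 &&
              any(sqrt(colSums((t(centres_used) - c_mm)^2)) < 10.5))
            next
          ball <- ball_mask(ax, c_mm, r_s)
          if (!any(ball) || any(ball & !allowed) || any(ball & out)) next
          out <- out | ball
          centres_used <- rbind(centres_used, c_mm)
          planted <- planted + 1L
          break
        }
      }
    }
    res <- binary_volume(out, sp, affine = mask$affine)
    attr(res, "degrade_meta") <- list(dropped = dropped, n_spurious = planted)
    res
  })
}
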