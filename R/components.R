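#' Labelled connected components (lesion map)
#'
#' Labels maximal connected sets of foreground voxels; each component is one
#' lesion. Connectivity 6 joins face neighbours, 18 adds edges, 26 the full
#' 3x3x3 neighbourhood (the default: the natural 3-D reading of "connected"
#' for blobby lesions). Label 0 is background; components are numbered 1..n
#' in scan order.
#'
#' @param mask a [binary_volume()].
#' @param connectivity 6, 18 or 26.
#' @return an object of class `lesion_map` with fields `labels` (integer
#'   array), `n` (component count), `voxel_counts`, `volumes_mm3` (per-lesion,
#'   voxel count times voxel volume), `spacing`, `connectivity`.
#' @examples
#' m <- binary_volume(array(FALSE, c(4, 4, 1)))
#' m$data[1, 1, 1] <- TRUE; m$data[3, 3, 1] <- TRUE
#' connected_components(m, connectivity = 6)$n
#' @export
connected_components <- function(mask, connectivity = 26) {
  stopifnot(is_binary_volume(mask))
  lab <- label_components_cpp(as.logical(mask$data), dim(mask$data),
                              as.integer(connectivity))
  dim(lab) <- dim(mask$data)
  n <- max(lab)
  counts <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  structure(list(labels = lab, n = n, voxel_counts = counts,
                 volumes_mm3 = counts * prod(mask$spacing),
                 spacing = mask$spacing, connectivity = connectivity),
            class = "lesion_map")
}

#' @export
print.lesion_map <- function(x, ...) {
  cat(sprintf("<lesion_map> %d lesion(s), connectivity %d\n",
              x$n, x$connectivity))
  if (x$n > 0)
    cat("  volumes (mm^3):",
        paste(format(round(x$volumes_mm3, 1), trim = TRUE), collapse = ", "),
        "\n")
  invisible(x)
}

#' Extract one lesion as a mask
#'
#' @param lesions a `lesion_map`.
#' @param label lesion label (1..n).
#' @return a [binary_volume()] of that single component.
#' @export
lesion_mask <- function(lesions, label) {
  stopifnot(inherits(lesions, "lesion_map"))
  if (label < 1 || label > lesions$n) stop("no lesion with label ", label)
  binary_volume(lesions$labels == label, spacing = lesions$spacing)
}

#' @rdname connected_components
#' @param x a `lesion_map`.
#' @export
as_binary_volume <- function(x) {
  stopifnot(inherits(x, "lesion_map"))
  binary_volume(x$labels > 0L, spacing = x$spacing)
}

# internal constructor used when a labels array is filtered elsewhere
lesion_map_from_labels <- function(labels, spacing, connectivity) {
  n <- max(labels)
  counts <- if (n > 0) tabulate(labels[labels > 0L], nbins = n) else integer(0)
  structure(list(labels = labels, n = n, voxel_counts = counts,
                 volumes_mm3 = counts * prod(spacing),
                 spacing = spacing, connectivity = connectivity),
            class = "lesion_map")
}
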