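#' Read a binary mask from a NIfTI file
#'
#' Reads a 3-D NIfTI volume (or 4-D with singleton trailing axis), takes the
#' voxel spacing from the header `pixdim`, and binarizes voxel values at
#' `binarize_threshold` (strictly greater than). The full header image is kept
#' in the `affine` slot so writes preserve placement metadata.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param binarize_threshold voxels with value strictly above this are
#'   foreground; default 0.5 suits \{0,1\} masks.
#' @return a [binary_volume()].
#' @export
read_mask <- function(path, binarize_threshold = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop("expected a 3-D volume, got ", length(d), "-D payload in ", path)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in header of ", path)
  binary_volume(img2 > binarize_threshold, spacing = spacing, affine = img)
}

#' Write a binary mask or label map as NIfTI
#'
#' Masks are written as unsigned 8-bit \{0,1\}; label maps as unsigned 16-bit
#' label volumes. Header spacing (and, when the volume came from a file, its
#' affine) is preserved.
#'
#' @param vol a [binary_volume()] (for `write_mask`) or a [lesion_map()]
#'   (for `write_lesion_map`).
#' @param path destination `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_mask <- function(vol, path) {
  stopifnot(is_binary_volume(vol))
  arr <- array(as.integer(vol$data), dim = dim(vol$data))
  img <- if (!is.null(vol$affine)) RNifti::asNifti(arr, reference = vol$affine)
         else RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
write_lesion_map <- function(vol, path) {
  stopifnot(inherits(vol, "lesion_map"))
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "uint16")
  invisible(path)
}
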