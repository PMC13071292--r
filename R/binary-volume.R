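#' Binary voxel volume with physical spacing
#'
#' `binary_volume()` wraps a 3-D logical array together with its voxel spacing
#' (mm per voxel along each axis) and optional affine/origin metadata carried
#' through from a NIfTI header. It is the mask currency of the package: every
#' morphology, metric and set operation consumes and returns `binary_volume`
#' objects and refuses to mix incompatible grids (identical shape *and*
#' spacing are required; there is never silent resampling).
#'
#' @param data logical (or coercible) 3-D array of voxel values.
#' @param spacing numeric length-3, mm per voxel along each axis; all
#'   components must be strictly positive and finite.
#' @param affine optional 4x4 affine (or any header payload) carried through
#'   unmodified; `NULL` when the volume was built in memory.
#'
#' @return An object of class `binary_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @examples
#' v <- binary_volume(array(FALSE, c(4, 4, 2)), spacing = c(0.5, 0.5, 2.5))
#' bv_count(v)
#' @export
binary_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    dim(data) <- dim(data)[1:3]
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (or 4-D with a singleton trailing axis)")
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
    data[is.na(data)] <- FALSE
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf(
    "<binary_volume> %s voxels @ (%s) mm | %d foreground (%.1f mm^3)\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = ", "),
    bv_count(x), bv_volume_mm3(x)))
  invisible(x)
}

#' @export
dim.binary_volume <- function(x) dim(x$data)

#' @export
as.array.binary_volume <- function(x, ...) x$data

is_binary_volume <- function(x) inherits(x, "binary_volume")

#' Grid compatibility check
#'
#' Stops unless both volumes share shape and spacing. All set operations and
#' metrics call this; mixing grids is an error, never a resample.
#'
#' @param a,b `binary_volume` objects.
#' @return Invisibly `TRUE`.
#' @export
bv_check_compatible <- function(a, b) {
  stopifnot(is_binary_volume(a), is_binary_volume(b))
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: shapes differ (", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"), ")")
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 0)))
    stop("grid mismatch: voxel spacings differ")
  invisible(TRUE)
}

bv_like <- function(template, data) {
  binary_volume(data, spacing = template$spacing, affine = template$affine)
}

#' Voxel set operations
#'
#' Elementwise conjunction, disjunction, complement and difference of masks on
#' the same grid, plus foreground counting and physical volume.
#'
#' @param a,b `binary_volume` objects on identical grids.
#' @return `bv_and`, `bv_or`, `bv_not`, `bv_diff` return a `binary_volume`;
#'   `bv_count` the number of foreground voxels; `bv_volume_mm3` the foreground
#'   volume in cubic millimetres (count times voxel volume).
#' @name bv-set-ops
NULL

#' @rdname bv-set-ops
#' @export
bv_and <- function(a, b) { bv_check_compatible(a, b); bv_like(a, a$data & b$data) }

#' @rdname bv-set-ops
#' @export
bv_or <- function(a, b) { bv_check_compatible(a, b); bv_like(a, a$data | b$data) }

#' @rdname bv-set-ops
#' @export
bv_not <- function(a) { stopifnot(is_binary_volume(a)); bv_like(a, !a$data) }

#' @rdname bv-set-ops
#' @export
bv_diff <- function(a, b) { bv_check_compatible(a, b); bv_like(a, a$data & !b$data) }

#' @rdname bv-set-ops
#' @export
bv_count <- function(a) { stopifnot(is_binary_volume(a)); sum(a$data) }

#' @rdname bv-set-ops
#' @export
bv_volume_mm3 <- function(a) bv_count(a) * prod(a$spacing)

#' Physical voxel-centre coordinates of foreground voxels
#'
#' Returns an n x 3 matrix of physical positions (mm) of the centres of all
#' foreground voxels, using 0-based voxel indices scaled by spacing.
#'
#' @param a a `binary_volume`.
#' @return numeric matrix with one row per foreground voxel.
#' @export
bv_coords_mm <- function(a) {
  stopifnot(is_binary_volume(a))
  idx <- which(a$data, arr.ind = TRUE)
  sweep(idx - 1, 2, a$spacing, `*`)
}
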