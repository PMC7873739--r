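#' CT volume container
#'
#' A 3D voxel grid of Hounsfield units with isotropic or anisotropic spacing.
#' Voxel `[i, j, k]` (1-based in R) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing` in right-handed patient-space mm.
#'
#' @param voxels 3D numeric array of HU.
#' @param spacing mm per axis; scalar or length 3, all > 0.
#' @param origin mm position of the centre of the first voxel.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3, length(voxels) > 0)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel-centre world coordinates along each axis
#' @param volume A [ct_volume()] (or compatible mask object).
#' @return List of three numeric vectors (x, y, z voxel-centre mm).
#' @export
voxel_axes <- function(volume) {
  d <- dim(volume$voxels %||% volume$mask)
  lapply(1:3, function(a) volume$origin[a] + (seq_len(d[a]) - 1) * volume$spacing[a])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All voxel-centre coordinates of a mask or volume subset
#'
#' @param volume A [ct_volume()] or mask object.
#' @param which Logical array selecting voxels (default: all).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(volume, which = NULL) {
  arr <- volume$voxels %||% volume$mask
  d <- dim(arr)
  idx <- if (is.null(which)) seq_len(prod(d)) else which(which)
  ijk <- arrayInd(idx, d) - 1L
  sweep(sweep(ijk, 2, volume$spacing, `*`), 2, volume$origin, `+`)
}

#' Write a volume to NIfTI
#'
#' Voxel spacing is carried in `pixdim` and the origin in the sform/qform
#' translation, so the voxel-centre convention round-trips.
#'
#' @param volume A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  xf <- diag(4)
  diag(xf)[1:3] <- volume$spacing
  xf[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(img, reference = NULL)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#' @param path NIfTI file path.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  org <- xf[1:3, 4]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  ct_volume(arr, spacing = sp, origin = org)
}
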