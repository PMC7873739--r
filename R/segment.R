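#' Threshold-based bone segmentation
#'
#' Thresholds the volume to `[lower_hu, upper_hu]`, keeps the largest
#' 26-connected component, then fills internal holes slice-by-slice in 2D,
#' preserving the outer contour — so a cortical shell encloses a homogeneously
#' filled mask even when the trabecular interior falls below the threshold.
#'
#' @param volume A [ct_volume()].
#' @param lower_hu,upper_hu HU window, `lower_hu < upper_hu`.
#' @param fill_axis Axis (1, 2 or 3) perpendicular to the 2D filling slices.
#' @return A mask object (class `ct_mask`): logical array plus the parent
#'   volume's spacing/origin.
#' @export
segment <- function(volume, lower_hu, upper_hu = Inf, fill_axis = 3) {
  stopifnot(lower_hu < upper_hu)
  m <- volume$voxels >= lower_hu & volume$voxels <= upper_hu
  if (!any(m)) stop("segmentation produced an empty mask in the given HU window")
  lab <- .label_components_cpp(m, dim(m))
  keep <- which.max(lab$sizes)
  m <- lab$labels == keep
  if (fill_axis != 3) {
    perm <- switch(fill_axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2))
    mp <- aperm(m, perm)
    mp <- array(.fill_holes_2d_cpp(mp, dim(mp)), dim(mp))
    m <- aperm(mp, order(perm))
  } else {
    m <- array(.fill_holes_2d_cpp(m, dim(m)), dim(m))
  }
  structure(list(mask = m, spacing = volume$spacing, origin = volume$origin),
            class = "ct_mask")
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("ct_mask: %s voxels set of %s (%.1f mm^3)\n",
              format(sum(x$mask), big.mark = ","),
              format(length(x$mask), big.mark = ","),
              sum(x$mask) * prod(x$spacing)))
  invisible(x)
}

#' Mask volume in mm^3
#' @param mask A `ct_mask`.
#' @export
mask_volume <- function(mask) sum(mask$mask) * prod(mask$spacing)
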