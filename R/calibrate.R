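#' Rod geometry description for the calibration phantom
#'
#' Parallel cylindrical rods of known equivalent bone mineral density.
#' Rods are parallel to one coordinate axis.
#'
#' @param centers n x 3 matrix of rod axis reference points, mm.
#' @param radius Rod radius, mm.
#' @param axis Axis index the rods run along (1, 2, or 3).
#' @param half_length Rod half-length along `axis`, mm.
#' @param densities Known equivalent BMD per rod, g/cm^3.
#' @export
rod_geometry <- function(centers, radius, axis = 2, half_length = 12,
                         densities) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, radius > 0, axis %in% 1:3,
            nrow(centers) == length(densities), all(densities >= 0))
  structure(list(centers = centers, radius = radius, axis = axis,
                 half_length = half_length, densities = as.numeric(densities)),
            class = "rod_geometry")
}

#' Sample calibration rod HU means from a volume
#'
#' Computes the mean HU over each rod's interior. The sampled region is the
#' rod cylinder eroded by one voxel radially and axially, so partial-volume
#' voxels at the rod boundary do not bias the mean.
#'
#' @param volume A [ct_volume()].
#' @param rods A [rod_geometry()].
#' @return A data.frame of class `calibration_samples` with columns
#'   `mean_hu`, `known_density`, `n_voxels`.
#' @export
sample_rods <- function(volume, rods) {
  ax <- voxel_axes(volume)
  erode <- max(volume$spacing)
  radial_axes <- setdiff(1:3, rods$axis)
  out <- lapply(seq_len(nrow(rods$centers)), function(r) {
    ctr <- rods$centers[r, ]
    # radial distance field over the two cross-axes, vectorised outer sum
    d2 <- outer((ax[[radial_axes[1]]] - ctr[radial_axes[1]])^2,
                (ax[[radial_axes[2]]] - ctr[radial_axes[2]])^2, `+`)
    in_disc <- d2 <= (rods$radius - erode)^2
    along <- abs(ax[[rods$axis]] - ctr[rods$axis]) <= rods$half_length - erode
    # build full logical array in the volume's axis order
    perm <- order(c(radial_axes, rods$axis))
    full <- outer(in_disc, along)  # dims: radial1, radial2, axis
    sel <- array(aperm(full, perm) > 0, dim(volume$voxels))
    n <- sum(sel)
    if (n == 0) stop(sprintf("rod %d region contains no voxels", r))
    data.frame(mean_hu = mean(volume$voxels[sel]),
               known_density = rods$densities[r], n_voxels = n)
  })
  out <- do.call(rbind, out)
  class(out) <- c("calibration_samples", "data.frame")
  out
}

#' Fit the HU to density calibration line
#'
#' Ordinary least-squares fit of `density = a + b * HU` to phantom rod
#' samples, the first step of the two-step material mapping.
#'
#' @param samples A `calibration_samples` data.frame (or any data.frame with
#'   `mean_hu` and `known_density` columns), at least two distinct HU values.
#' @return A [linear_law()] (HU -> g/cm^3) with attributes `r_squared` and
#'   `fit` (the underlying `lm` object).
#' @export
fit_hu_to_density <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("mean_hu", "known_density") %in% names(samples)))
  if (nrow(samples) < 2) stop("at least two rods are required")
  if (diff(range(samples$mean_hu)) < 1e-9)
    stop("degenerate calibration: all rod HU values are equal")
  fit <- stats::lm(known_density ~ mean_hu, data = samples)
  law <- linear_law(stats::coef(fit)[[1]], stats::coef(fit)[[2]],
                    input = "HU", output = "g/cm^3")
  # summary.lm warns on exact fits; noiseless calibrations are expected here
  attr(law, "r_squared") <- suppressWarnings(summary(fit)$r.squared)
  attr(law, "fit") <- fit
  law
}
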