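#' 3D line (axis)
#'
#' A point and a unit direction; the direction is orientation-free for angle
#' purposes (`v` and `-v` describe the same axis).
#' @param point A point on the line, mm.
#' @param direction Direction vector (normalised internally).
#' @export
line3d <- function(point, direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / nrm),
            class = "line3d")
}

#' @export
print.line3d <- function(x, ...) {
  cat(sprintf("line3d: point (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Transform a line by a rigid transform
#' @param line A [line3d()].
#' @param transform A [rigid_transform()].
#' @export
transform_line <- function(line, transform) {
  line3d(transform_points(transform, line$point),
         transform_directions(transform, line$direction))
}

#' 3D line-to-line angle
#'
#' `alpha = acos(|a . b|)` in degrees — symmetric, orientation-free, in
#' `[0, 90]`.
#' @param a,b [line3d()] objects (or unit vectors).
#' @return Angle in degrees.
#' @export
angle_between <- function(a, b) {
  da <- if (inherits(a, "line3d")) a$direction else a / sqrt(sum(a^2))
  db <- if (inherits(b, "line3d")) b$direction else b / sqrt(sum(b^2))
  acos(min(1, abs(sum(da * db)))) * 180 / pi
}

#' Distance from points to a line
#' @param line A [line3d()].
#' @param pts n x 3 points.
#' @export
line_point_distance <- function(line, pts) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1, 3) else as.matrix(pts)
  rel <- sweep(p, 2, line$point)
  s <- as.numeric(rel %*% line$direction)
  d <- sqrt(pmax(rowSums(rel^2) - s^2, 0))
  if (vec) d[1] else d
}

#' Fit a cylinder axis to a point cloud
#'
#' Total-least-squares line through the points: the axis passes through the
#' centroid along the principal direction of the covariance. The radius is
#' refit orthogonally afterwards and compared with the expected drill-bit
#' diameter as a sanity check (warn on > 20 % deviation). Point clouds with
#' no dominant axis (near-isotropic) are rejected.
#'
#' @param points n x 3 matrix (n >= 6), e.g. metal voxel centres of a drill
#'   bit.
#' @param expected_diameter Nominal cylinder diameter, mm (NULL to skip the
#'   check).
#' @param solid Whether the points fill the cylinder (voxel samples of a
#'   solid bit) or lie on its surface; sets the radius estimator.
#' @return A [line3d()] with attributes `radius` (fitted, mm) and
#'   `elongation` (principal-axis anisotropy ratio).
#' @export
fit_cylinder_axis <- function(points, expected_diameter = NULL,
                              solid = TRUE) {
  P <- as.matrix(points)
  if (nrow(P) < 6) stop("at least 6 points are required")
  ctr <- colMeans(P)
  cv <- stats::cov(P)
  eig <- eigen(cv, symmetric = TRUE)
  elong <- sqrt(eig$values[1] / max(eig$values[2], 1e-300))
  if (elong < 2)
    stop("point cloud has no dominant axis (isotropic); cylinder axis undefined")
  ax <- line3d(ctr, eig$vectors[, 1])
  r <- line_point_distance(ax, P)
  radius <- if (solid) sqrt(2 * mean(r^2)) else sqrt(mean(r^2))
  attr(ax, "radius") <- radius
  attr(ax, "elongation") <- elong
  if (!is.null(expected_diameter)) {
    if (abs(2 * radius - expected_diameter) > 0.2 * expected_diameter)
      warning(sprintf(
        "fitted diameter %.2f mm deviates > 20%% from expected %.2f mm",
        2 * radius, expected_diameter))
  }
  ax
}
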