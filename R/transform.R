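#' Rigid transform (rotation + translation)
#'
#' A proper rigid body motion in 3D: `y = R x + t`, with `R` a 3x3 rotation
#' matrix (orthonormal, det = +1) and `t` a translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation matrix has negative determinant (reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Apply a rigid transform to directions (rotation only)
#' @inheritParams transform_points
#' @export
transform_directions <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$rotation)
  if (vec) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula.
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix, degrees
#' @param R 3x3 rotation matrix.
#' @export
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c_))) * 180 / pi
}

#' Least-squares rigid registration of paired landmarks
#'
#' Closed-form orthogonal Procrustes (Kabsch) fit of the proper rigid
#' transform minimising `sum || R s_i + t - x_i ||^2` over corresponding
#' source/target pairs. Reflections are excluded: the returned rotation always
#' has determinant +1.
#'
#' @param source_pts,target_pts n x 3 matrices of corresponding points (n >=
#'   3, non-collinear).
#' @return A [rigid_transform()] with attribute `rms` (root-mean-square
#'   residual, mm).
#' @export
landmark_register <- function(source_pts, target_pts) {
  S <- as.matrix(source_pts); X <- as.matrix(target_pts)
  stopifnot(ncol(S) == 3, ncol(X) == 3)
  if (nrow(S) != nrow(X)) stop("source and target must pair one-to-one")
  if (nrow(S) < 3) stop("at least 3 landmark pairs are required")
  cs <- colMeans(S); cx <- colMeans(X)
  S0 <- sweep(S, 2, cs); X0 <- sweep(X, 2, cx)
  sv <- svd(crossprod(X0, S0))  # H = X0^T S0, R = U diag(1,1,d) V^T
  # collinearity check: second singular value vanishing means the points do
  # not determine a unique rotation
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("landmarks are collinear or degenerate; rotation is not determined")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cx - as.numeric(R %*% cs)
  tr <- rigid_transform(R, t)
  res <- transform_points(tr, S) - X
  attr(tr, "rms") <- sqrt(mean(rowSums(res^2)))
  tr
}
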