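#' Iterative-closest-point registration refinement
#'
#' Point-to-plane ICP from an initial rigid estimate (typically the landmark
#' fit): per iteration, source sample points are matched to their closest
#' points on the target surface, the worst 10 % of matches are trimmed, and
#' the trimmed point-to-plane error is minimised by a linearised rigid
#' update. Convergence is declared when the RMS changes by less than `tol`;
#' five consecutive RMS increases abort with an error.
#'
#' @param source_mesh,target_mesh [surface_mesh()] objects with initial
#'   overlap under `init`.
#' @param init Initial [rigid_transform()].
#' @param max_iter Maximum iterations.
#' @param trim Fraction of best matches kept.
#' @param tol RMS-change convergence threshold, mm.
#' @param n_sample Maximum number of source sample points.
#' @return A [rigid_transform()] with attributes `rms` (final trimmed RMS,
#'   mm) and `iterations`.
#' @export
refine_register <- function(source_mesh, target_mesh, init = rigid_transform(),
                            max_iter = 50, trim = 0.9, tol = 1e-4,
                            n_sample = 1500) {
  S <- source_mesh$vertices
  if (nrow(S) > n_sample)
    S <- S[round(seq(1, nrow(S), length.out = n_sample)), , drop = FALSE]
  tn <- mesh_face_normals(target_mesh)
  Tcur <- init
  # overlap sanity: under init, the median match distance must be small
  # relative to the target size
  cp0 <- closest_point_on_mesh(transform_points(Tcur, S), target_mesh)
  diam <- sqrt(sum((apply(target_mesh$vertices, 2, max) -
                    apply(target_mesh$vertices, 2, min))^2))
  if (stats::median(cp0$distance) > 0.5 * diam)
    stop("meshes do not overlap under the initial transform")
  rms_prev <- Inf
  grow <- 0
  best <- list(T = Tcur, rms = Inf, it = 0)
  for (it in seq_len(max_iter)) {
    P <- transform_points(Tcur, S)
    cp <- closest_point_on_mesh(P, target_mesh)
    keep <- order(cp$distance)[seq_len(floor(trim * nrow(P)))]
    p <- P[keep, , drop = FALSE]
    q <- cp$point[keep, , drop = FALSE]
    n <- tn[cp$face[keep], , drop = FALSE]
    b <- rowSums(n * (q - p))
    rms <- sqrt(mean(b^2))
    if (rms < best$rms) best <- list(T = Tcur, rms = rms, it = it)
    if (abs(rms_prev - rms) < tol) break
    if (rms > rms_prev) {
      grow <- grow + 1
      if (grow >= 5) stop("ICP diverged: RMS grew 5 consecutive iterations ",
                          sprintf("(rms %.4g mm)", rms))
    } else grow <- 0
    rms_prev <- rms
    # linearised point-to-plane update: rows [ (p x n)', n' ] [w; t] = b
    A <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
               p[, 3] * n[, 1] - p[, 1] * n[, 3],
               p[, 1] * n[, 2] - p[, 2] * n[, 1],
               n)
    x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) stop("ICP normal equations singular: ",
                                           conditionMessage(e)))
    w <- x[1:3]; tr <- x[4:6]
    ang <- sqrt(sum(w^2))
    Rd <- if (ang < 1e-14) diag(3) else
      rotation_about_axis(w / ang, ang * 180 / pi)
    Tcur <- compose_transforms(rigid_transform(Rd, tr), Tcur)
  }
  out <- best$T
  attr(out, "rms") <- best$rms
  attr(out, "iterations") <- best$it
  out
}
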