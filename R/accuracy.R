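#' Gertzbein-Robbins grading of a realized trajectory
#'
#' Measures how far the realized screw cylinder protrudes outside the safe
#' corridor wall and maps the breach distance to the standard 2 mm grading
#' bands: A = 0 (fully contained), B = (0, 2], C = (2, 4], D = (4, 6],
#' E = > 6 mm.
#'
#' @param realized A [line3d()] realized axis (plan frame).
#' @param screw A [screw_spec()] — the screw that will follow the drilled
#'   path (its radius defines the realized cylinder).
#' @param bone The planning bone [surface_mesh()] (used to clip the
#'   evaluation to the inserted span).
#' @param corridor List `axis` ([line3d()]) and `radius` (mm): the safe
#'   corridor around the planned axis.
#' @param n_samples Axial sampling resolution.
#' @return List: `grade` (factor A-E), `breach_mm`, `max_deviation_mm` (axis
#'   offset at the worst sample).
#' @export
grade_trajectory <- function(realized, screw, bone, corridor,
                             n_samples = 200) {
  hits <- line_mesh_intersections(realized$point, realized$direction, bone)
  if (length(hits) < 2) stop("realized axis does not intersect the bone")
  t_in <- hits[1]
  s <- seq(t_in, t_in + screw$length, length.out = n_samples)
  pts <- outer(s, realized$direction) +
    matrix(realized$point, n_samples, 3, byrow = TRUE)
  dev <- line_point_distance(corridor$axis, pts)
  breach <- max(dev + screw$diameter / 2 - corridor$radius, 0)
  grade <- cut(breach, c(-Inf, 0, 2, 4, 6, Inf),
               labels = c("A", "B", "C", "D", "E"))
  list(grade = as.character(grade), breach_mm = breach,
       max_deviation_mm = max(dev))
}

#' Audit drilling accuracy against the virtual plan
#'
#' The full accuracy instrument: segments the metal drill bits from the
#' post-drill CT, reconstructs the drilled bone model surface, registers the
#' post-drill scene back to the planning frame (landmark Procrustes fit
#' followed by trimmed point-to-plane ICP), fits a cylinder axis to each
#' bit, matches bits to planned trajectories, and reports the 3D line-to-line
#' angle, entry offset, breach distance and Gertzbein-Robbins grade per
#' trajectory.
#'
#' @param plans Named list of [trajectory_plan()] objects (the virtual plan).
#' @param postdrill_volume [ct_volume()] of the drilled model (metal-HU bits
#'   present). If it carries a `landmarks` element it is used when
#'   `landmarks` is NULL.
#' @param plan_bone Planning-frame bone [surface_mesh()].
#' @param landmarks List with `post` and `plan` corresponding landmark
#'   matrices (mm).
#' @param metal_hu Metal threshold, HU.
#' @param bone_window HU window for the model surface.
#' @param bit_diameter Expected drill bit diameter, mm.
#' @param corridor_clearance Safe-corridor radius margin beyond the screw
#'   radius, mm.
#' @param refine Run the ICP refinement stage after the landmark fit.
#' @return An `accuracy_report`: per-trajectory data.frame plus registration
#'   diagnostics.
#' @export
evaluate_drilling <- function(plans, postdrill_volume, plan_bone,
                              landmarks = NULL, metal_hu = 2000,
                              bone_window = c(200, 1500),
                              bit_diameter = 2.5, corridor_clearance = 4,
                              refine = TRUE) {
  if (is.null(landmarks)) landmarks <- postdrill_volume$landmarks
  if (is.null(landmarks)) stop("registration landmarks are required")

  # drill bits: metal components in the post-drill frame
  metal <- postdrill_volume$voxels >= metal_hu
  if (!any(metal)) stop("post-drill volume contains no metal-HU voxels")
  lab <- .label_components_cpp(metal, dim(metal))
  comp_ids <- which(lab$sizes >= 30)  # ignore speckle
  if (length(comp_ids) != length(plans))
    stop(sprintf("found %d drill bits but %d planned trajectories",
                 length(comp_ids), length(plans)))
  bit_axes <- lapply(comp_ids, function(ci) {
    pts <- voxel_centers(postdrill_volume, lab$labels == ci)
    fit_cylinder_axis(pts, expected_diameter = bit_diameter)
  })

  # registration: landmark Procrustes, then ICP on the model surface
  T0 <- landmark_register(landmarks$post, landmarks$plan)
  rms0 <- attr(T0, "rms")
  Treg <- T0
  icp_rms <- NA_real_
  if (refine) {
    bone_mask <- tryCatch(
      segment(postdrill_volume, bone_window[1], bone_window[2]),
      error = function(e) NULL)
    if (!is.null(bone_mask)) {
      post_mesh <- extract_surface(bone_mask)
      Treg <- refine_register(post_mesh, plan_bone, T0)
      icp_rms <- attr(Treg, "rms")
    }
  }
  axes_plan_frame <- lapply(bit_axes, transform_line, transform = Treg)

  # match bits to plans by angle + entry proximity
  rows <- lapply(names(plans), function(nm) {
    pl <- plans[[nm]]
    plan_axis <- line3d(pl$entry, pl$direction)
    score <- vapply(axes_plan_frame, function(ax)
      line_point_distance(ax, pl$entry) + angle_between(ax, plan_axis),
      numeric(1))
    ax <- axes_plan_frame[[which.min(score)]]
    g <- grade_trajectory(ax, pl$screw, plan_bone,
                          corridor = list(axis = plan_axis,
                                          radius = pl$screw$diameter / 2 +
                                            corridor_clearance))
    data.frame(trajectory = nm,
               angle_deg = angle_between(ax, plan_axis),
               entry_offset_mm = line_point_distance(ax, pl$entry),
               breach_mm = g$breach_mm, grade = g$grade)
  })
  report <- do.call(rbind, rows)
  structure(list(per_trajectory = report,
                 registration = list(landmark_rms_mm = rms0,
                                     icp_rms_mm = icp_rms,
                                     transform = Treg)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report\n")
  print(x$per_trajectory, row.names = FALSE)
  cat(sprintf("  registration RMS: landmarks %.4g mm, ICP %.4g mm\n",
              x$registration$landmark_rms_mm, x$registration$icp_rms_mm))
  invisible(x)
}
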