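#' Pedicle screw specification
#'
#' Default dimensions follow a 45 mm x 6.5 mm monoaxial pedicle screw; the
#' head is an idealised cylindrical monoaxial tulip. The thread is a
#' visualisation option only — the analysis geometry is the smooth shaft,
#' matching the tied-interface idealisation.
#'
#' @param length Shaft length (tip to entry plane at full insertion), mm.
#' @param diameter Shaft outer diameter, mm.
#' @param head_diameter,head_height Head cylinder dimensions, mm.
#' @param head_offset Neck length between the insertion plane and the head
#'   underside, mm — keeps the head clear of the cortex so the tied
#'   interface acts along the shaft, not under the head.
#' @param thread Render a decorative thread profile on the shaft.
#' @export
screw_spec <- function(length = 45, diameter = 6.5, head_diameter = 10,
                       head_height = 9, head_offset = 8, thread = FALSE) {
  stopifnot(length > 0, diameter > 0, head_diameter > 0, head_height > 0,
            head_offset >= 0)
  structure(list(length = length, diameter = diameter,
                 head_diameter = head_diameter, head_height = head_height,
                 head_offset = head_offset, thread = thread),
            class = "screw_spec")
}

#' Parametric screw surface model
#'
#' Builds a watertight solid of revolution aligned to +z with the shaft tip
#' at the origin: shaft cylinder over z in [0, length], head cylinder over
#' [length, length + head_height].
#'
#' @param spec A [screw_spec()].
#' @param segments Circumferential tessellation.
#' @return A watertight [surface_mesh()].
#' @export
make_screw <- function(spec, segments = 48) {
  stopifnot(inherits(spec, "screw_spec"))
  rs <- spec$diameter / 2
  rh <- spec$head_diameter / 2
  L <- spec$length; H <- spec$head_height
  Ln <- L + spec$head_offset   # shaft + neck, then the head
  if (spec$thread) {
    nz <- max(24, round(L / 1))
    zs <- seq(0, L, length.out = nz)
    pitch <- 2.5; depth <- 0.25 * rs
    prof_z <- c(zs, Ln, Ln, Ln + H)
    prof_r <- c(rs - depth / 2 + (depth / 2) * sin(2 * pi * zs / pitch),
                rs, rh, rh)
    prof_r[1] <- rs - depth  # taper the tip ring slightly
  } else {
    prof_z <- c(0, Ln, Ln, Ln + H)
    prof_r <- c(rs, rs, rh, rh)
  }
  revolve_profile(prof_r, prof_z, segments)
}

# closed solid of revolution about +z from a radius/height profile
revolve_profile <- function(radii, heights, segments) {
  th <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  nr <- length(radii)
  V <- do.call(rbind, lapply(seq_len(nr), function(i)
    cbind(radii[i] * cos(th), radii[i] * sin(th), heights[i])))
  ring <- function(i) (i - 1) * segments + seq_len(segments)
  nxt <- c(2:segments, 1)
  F <- list()
  for (i in seq_len(nr - 1)) {
    a <- ring(i); b <- ring(i + 1)
    # outward-facing strip (counter-clockwise seen from outside)
    F[[length(F) + 1]] <- cbind(a, a[nxt], b[nxt])
    F[[length(F) + 1]] <- cbind(a, b[nxt], b)
  }
  cb <- nrow(V) + 1  # bottom pole
  ct <- nrow(V) + 2  # top pole
  V <- rbind(V, c(0, 0, heights[1]), c(0, 0, heights[nr]))
  bot <- ring(1); top <- ring(nr)
  F[[length(F) + 1]] <- cbind(rep(cb, segments), bot[nxt], bot)  # normal -z
  F[[length(F) + 1]] <- cbind(rep(ct, segments), top, top[nxt])  # normal +z
  weld_vertices(surface_mesh(V, do.call(rbind, F)))
}

#' Screw trajectory plan
#'
#' A labelled screw axis: entry point on the bone surface and unit insertion
#' direction (pointing into the bone), plus the screw to insert.
#'
#' @param label Trajectory label, e.g. `"S1"` (convergent) or `"ALA"`
#'   (divergent).
#' @param entry Entry point, mm.
#' @param direction Insertion direction (normalised internally).
#' @param screw A [screw_spec()].
#' @export
trajectory_plan <- function(label, entry, direction, screw = screw_spec()) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  structure(list(label = label, entry = as.numeric(entry),
                 direction = as.numeric(direction) / nrm, screw = screw),
            class = "trajectory_plan")
}

#' @export
print.trajectory_plan <- function(x, ...) {
  cat(sprintf("trajectory_plan %s: entry (%.1f, %.1f, %.1f), direction (%.3f, %.3f, %.3f)\n",
              x$label, x$entry[1], x$entry[2], x$entry[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# rotation taking +z to the given unit vector
rotation_z_to <- function(d) {
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  if (sum(v^2) < 1e-16) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Pose of a planned screw
#'
#' The rigid transform placing the canonical screw (tip at origin, +z toward
#' the head) on its planned trajectory: the tip sits at
#' `entry + length * direction`, the head protrudes at the entry side.
#' @param plan A [trajectory_plan()].
#' @return A [rigid_transform()].
#' @export
screw_pose <- function(plan) {
  R <- rotation_z_to(-plan$direction)
  rigid_transform(R, plan$entry + plan$screw$length * plan$direction)
}

#' Bone / implant assembly
#'
#' @param bone Bone [surface_mesh()].
#' @param fragment Optional retained-fragment [surface_mesh()].
#' @param screws Named list of placed screw meshes.
#' @export
assembly <- function(bone, fragment = NULL, screws = list()) {
  structure(list(bone = bone, fragment = fragment, screws = screws,
                 plans = list()),
            class = "assembly")
}

#' Virtually insert a screw along a planned trajectory
#'
#' Transforms the parametric screw to the plan pose, adds it to the assembly,
#' and reports the shaft length lying inside the bone and the number of
#' cortex crossings along the axis over the inserted span (entry included):
#' 2+ crossings is a bicortical purchase, 1 is monocortical.
#'
#' @param assy An [assembly()].
#' @param plan A [trajectory_plan()] whose axis intersects the bone.
#' @param segments Screw tessellation.
#' @return The updated assembly; the insertion report is appended to
#'   `assy$plans[[label]]` (`inserted_length_mm`, `cortex_crossings`,
#'   `bicortical`).
#' @export
place_screw <- function(assy, plan, segments = 48) {
  L <- plan$screw$length
  hits <- line_mesh_intersections(plan$entry, plan$direction, assy$bone)
  span <- hits[hits > -0.25 & hits < L + 0.25]
  if (length(hits) == 0 || length(span) == 0)
    stop(sprintf("trajectory %s does not intersect the bone", plan$label))
  crossings <- length(span)
  # inside intervals along the axis by parity of all crossings
  inside_len <- 0
  sh <- sort(hits)
  for (i in seq_len(length(sh) - 1)) {
    if (i %% 2 == 1) { # inside between odd and even crossing
      a <- max(sh[i], 0); b <- min(sh[i + 1], L)
      if (b > a) inside_len <- inside_len + (b - a)
    }
  }
  mesh <- transform_mesh(make_screw(plan$screw, segments), screw_pose(plan))
  assy$screws[[plan$label]] <- mesh
  assy$plans[[plan$label]] <- list(
    plan = plan,
    inserted_length_mm = inside_len,
    cortex_crossings = crossings,
    bicortical = crossings >= 2)
  assy
}

#' Clearance check between a planned screw and the retained fragment
#'
#' Minimum surface-to-surface distance between the planned screw solid and
#' the fragment mesh; overlapping solids report distance 0. Touching surfaces
#' at `clearance = 0` pass by definition (`distance >= clearance`).
#'
#' @param plan A [trajectory_plan()].
#' @param fragment Watertight fragment [surface_mesh()].
#' @param clearance Required clearance, mm.
#' @param segments Screw tessellation used for the distance query.
#' @return List: `distance_mm`, `pass`, `overlap`.
#' @export
check_collision <- function(plan, fragment, clearance = 1, segments = 96) {
  if (!is_watertight(fragment)) stop("fragment mesh must be watertight")
  screw <- transform_mesh(make_screw(plan$screw, segments), screw_pose(plan))
  d1 <- closest_point_on_mesh(screw$vertices, fragment)$distance
  d2 <- closest_point_on_mesh(fragment$vertices, screw)$distance
  overlap <- any(points_in_mesh(screw$vertices, fragment)) ||
    any(points_in_mesh(fragment$vertices, screw))
  dist <- if (overlap) 0 else min(d1, d2)
  list(distance_mm = dist, pass = dist >= clearance, overlap = overlap)
}
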