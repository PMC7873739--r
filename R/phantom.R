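#' Synthetic QCT phantom specification
#'
#' Describes a fully synthetic QCT-like scene: an in-line calibration phantom
#' with five rods of known equivalent BMD, a sacrum-like bone (elliptical
#' body plus an "ala" wing, cortical shell around a trabecular interior),
#' and an optional embedded metal screw fragment. The generating HU-density
#' law defaults to the packaged clinical calibration, so noiseless phantoms
#' round-trip it exactly.
#'
#' The trabecular density decreases smoothly from the body toward the ala
#' (the ala is the hypodense region of the sacrum), which is what makes the
#' divergent ala trajectory mechanically inferior to the convergent
#' bicortical one.
#'
#' @param voxel_spacing Isotropic voxel size, mm.
#' @param rod_densities Equivalent BMD of the calibration rods, g/cm^3,
#'   strictly increasing after sorting.
#' @param bone_shape List: `body_center`, `body_semi` (ellipsoid semi-axes,
#'   mm), optional `ala_center`/`ala_semi` (second ellipsoid; NULL for a
#'   plain ellipsoid), `cortical_thickness` (mm).
#' @param cortical_density Cortical shell apparent density, g/cm^3.
#' @param trabecular_density_range `c(low, high)` g/cm^3: ala end and body
#'   end of the smooth trabecular gradient.
#' @param fragment_pose NULL, or list `point`, `direction`, `length`,
#'   `diameter` (mm) of the retained broken-screw cylinder.
#' @param noise_sd Gaussian HU noise standard deviation (>= 0).
#' @param seed Integer seed governing all randomness.
#' @param hu_to_density The generating [linear_law()] (HU -> g/cm^3).
#' @param metal_hu Saturated HU rendered for metal.
#' @param soft_tissue_hu Background HU.
#' @param scale Isotropic scale factor applied to all geometry (reduced-size
#'   phantoms for fast meshing studies).
#' @param with_rods Include the calibration rod block.
#' @param margin Air/soft-tissue margin around the scene, mm.
#' @param supersample Sub-voxel sampling per axis for partial-volume
#'   rendering.
#' @export
phantom_spec <- function(
    voxel_spacing = 0.6,
    rod_densities = c(0, 0.05, 0.10, 0.15, 0.20),
    bone_shape = list(body_center = c(0, 0, 0), body_semi = c(26, 18, 15),
                      ala_center = c(34, 3, 3.5), ala_semi = c(30, 13, 7.5),
                      cortical_thickness = 2),
    cortical_density = 1.5,
    trabecular_density_range = c(0.03, 0.22),
    fragment_pose = list(point = c(-6, 8, -6), direction = c(-0.2, -0.97, 0),
                         length = 14, diameter = 4),
    noise_sd = 15, seed = 1L,
    hu_to_density = linear_law(-0.0829, 0.0026, "HU", "g/cm^3"),
    metal_hu = 3000, soft_tissue_hu = 20,
    scale = 1, with_rods = TRUE, margin = 4, supersample = 2) {
  stopifnot(voxel_spacing > 0, noise_sd >= 0, scale > 0, supersample >= 1)
  rs <- sort(rod_densities)
  if (any(rs < 0) || any(diff(rs) <= 0))
    stop("rod densities must be non-negative and strictly increasing after sorting")
  if (scale != 1) {
    bone_shape$body_center <- bone_shape$body_center * scale
    bone_shape$body_semi <- bone_shape$body_semi * scale
    if (!is.null(bone_shape$ala_center)) {
      bone_shape$ala_center <- bone_shape$ala_center * scale
      bone_shape$ala_semi <- bone_shape$ala_semi * scale
    }
    bone_shape$cortical_thickness <- bone_shape$cortical_thickness * scale
    if (!is.null(fragment_pose)) {
      fragment_pose$point <- fragment_pose$point * scale
      fragment_pose$length <- fragment_pose$length * scale
      fragment_pose$diameter <- fragment_pose$diameter * scale
    }
  }
  structure(list(
    voxel_spacing = voxel_spacing, rod_densities = rod_densities,
    bone_shape = bone_shape, cortical_density = cortical_density,
    trabecular_density_range = trabecular_density_range,
    fragment_pose = fragment_pose, noise_sd = noise_sd, seed = as.integer(seed),
    hu_to_density = hu_to_density, metal_hu = metal_hu,
    soft_tissue_hu = soft_tissue_hu, scale = scale, with_rods = with_rods,
    margin = margin, supersample = as.integer(supersample)),
    class = "phantom_spec")
}

# ---- implicit geometry -----------------------------------------------------

# smooth "inside bone" level function: g < 0 inside (min over ellipsoids of
# the normalised quadric minus 1)
phantom_bone_level <- function(spec, pts) {
  bs <- spec$bone_shape
  f <- ellipsoid_level(pts, bs$body_center, bs$body_semi)
  if (!is.null(bs$ala_center))
    f <- pmin(f, ellipsoid_level(pts, bs$ala_center, bs$ala_semi))
  f
}

ellipsoid_level <- function(pts, center, semi) {
  ((pts[, 1] - center[1]) / semi[1])^2 +
  ((pts[, 2] - center[2]) / semi[2])^2 +
  ((pts[, 3] - center[3]) / semi[3])^2 - 1
}

phantom_trabecular_level <- function(spec, pts) {
  bs <- spec$bone_shape
  t <- bs$cortical_thickness
  f <- ellipsoid_level(pts, bs$body_center, pmax(bs$body_semi - t, 1e-6))
  if (!is.null(bs$ala_center))
    f <- pmin(f, ellipsoid_level(pts, bs$ala_center,
                                 pmax(bs$ala_semi - t, 1e-6)))
  f
}

# apparent density of trabecular bone: density falls laterally toward the
# hypodense ala and rises toward the superior endplate (subchondral
# densification) — the two gradients that make the convergent corridor
# mechanically superior
phantom_trabecular_density <- function(spec, pts) {
  bs <- spec$bone_shape
  lo <- spec$trabecular_density_range[1]
  hi <- spec$trabecular_density_range[2]
  if (is.null(bs$ala_center)) return(rep(hi, nrow(pts)))
  # body: vertical gradient rising toward the superior endplate
  z0 <- bs$body_center[3] - bs$body_semi[3]
  s_sup <- pmin(pmax((pts[, 3] - z0) / (2 * bs$body_semi[3]), 0), 1)
  rho <- hi * (0.55 + 0.45 * s_sup)
  # ala interior: marrow-rich, near-uniform low density
  in_ala <- ellipsoid_level(pts, bs$ala_center,
                            pmax(bs$ala_semi - bs$cortical_thickness,
                                 1e-6)) <= 0
  in_body <- ellipsoid_level(pts, bs$body_center,
                             pmax(bs$body_semi - bs$cortical_thickness,
                                  1e-6)) <= 0
  rho[in_ala & !in_body] <- lo
  rho
}

# march from an interior point along a direction to the bone surface
phantom_surface_point <- function(spec, inside_pt, direction, step = 0.5,
                                  tol = 1e-9) {
  d <- direction / sqrt(sum(direction^2))
  g <- function(t) phantom_bone_level(spec, matrix(inside_pt + t * d, 1, 3))
  if (g(0) >= 0) stop("anchor point is not inside the bone")
  t1 <- step
  while (g(t1) < 0) t1 <- t1 + step
  lo <- t1 - step; hi <- t1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  inside_pt + ((lo + hi) / 2) * d
}

# fragment cylinder level (<0 inside); NULL-safe
phantom_fragment_inside <- function(spec, pts) {
  fp <- spec$fragment_pose
  if (is.null(fp)) return(rep(FALSE, nrow(pts)))
  inside_cylinder(pts, fp$point, fp$direction / sqrt(sum(fp$direction^2)),
                  fp$length, fp$diameter / 2)
}

inside_cylinder <- function(pts, base, dir, length, radius) {
  rel <- sweep(pts, 2, base)
  s <- rel %*% dir
  r2 <- rowSums(rel^2) - s^2
  s >= 0 & s <= length & r2 <= radius^2
}

# rod block geometry derived from the spec (rods below the bone, along y)
phantom_rods <- function(spec) {
  if (!spec$with_rods) return(NULL)
  bs <- spec$bone_shape
  zmin <- bs$body_center[3] - bs$body_semi[3]
  if (!is.null(bs$ala_center))
    zmin <- min(zmin, bs$ala_center[3] - bs$ala_semi[3])
  n <- length(spec$rod_densities)
  sc <- spec$scale
  centers <- cbind(bs$body_center[1] - 24 * sc + (seq_len(n) - 1) * 12 * sc,
                   bs$body_center[2],
                   zmin - 9 * sc)
  rod_geometry(centers, radius = 4 * sc, axis = 2, half_length = 12 * sc,
               densities = spec$rod_densities)
}

# ---- volume synthesis ------------------------------------------------------

# HU at arbitrary points (no noise): material priority
# fragment > bone (cortical/trabecular) > rods > soft tissue
phantom_hu_at <- function(spec, pts) {
  inv <- law_invert(spec$hu_to_density)
  hu <- rep(spec$soft_tissue_hu, nrow(pts))
  rods <- phantom_rods(spec)
  if (!is.null(rods)) {
    for (r in seq_len(nrow(rods$centers))) {
      ctr <- rods$centers[r, ]
      dirv <- c(0, 0, 0); dirv[rods$axis] <- 1
      base <- ctr; base[rods$axis] <- ctr[rods$axis] - rods$half_length
      sel <- inside_cylinder(pts, base, dirv, 2 * rods$half_length,
                             rods$radius)
      hu[sel] <- law_eval(inv, rods$densities[r])
    }
  }
  inb <- phantom_bone_level(spec, pts) <= 0
  if (any(inb)) {
    trab <- phantom_trabecular_level(spec, pts) <= 0
    rho <- numeric(nrow(pts))
    rho[inb & !trab] <- spec$cortical_density
    ti <- inb & trab
    rho[ti] <- phantom_trabecular_density(spec, pts[ti, , drop = FALSE])
    hu[inb] <- law_eval(inv, rho[inb])
  }
  frag <- phantom_fragment_inside(spec, pts)
  hu[frag] <- spec$metal_hu
  hu
}

#' Generate a synthetic QCT phantom volume with ground truth
#'
#' Renders the phantom scene into an HU volume with sub-voxel supersampling
#' (partial-volume boundaries) and additive Gaussian noise, and returns the
#' full generating truth: the HU-density law, analytic bone/fragment
#' surfaces, planned corridor axes, registration landmarks, the per-voxel
#' density field, and the rod geometry.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` (a [ct_volume()]) and `truth` (class
#'   `phantom_truth`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  bb <- phantom_bbox(spec)
  sp <- spec$voxel_spacing
  dims <- as.integer(ceiling((bb$hi - bb$lo) / sp)) + 1L
  origin <- bb$lo
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * sp)

  ss <- spec$supersample
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss * sp
  hu <- array(0, dims)
  occ_bone <- array(0, dims)
  nsub <- ss^3
  for (ox in offs) for (oy in offs) for (oz in offs) {
    # z-chunked evaluation to bound memory
    for (k0 in seq(1, dims[3], by = 16)) {
      ks <- k0:min(k0 + 15, dims[3])
      pts <- as.matrix(expand.grid(x = ax[[1]] + ox, y = ax[[2]] + oy,
                                   z = ax[[3]][ks] + oz))
      h <- phantom_hu_at(spec, pts)
      b <- phantom_bone_level(spec, pts) <= 0
      hu[, , ks] <- hu[, , ks, drop = FALSE] + array(h, c(dims[1], dims[2], length(ks)))
      occ_bone[, , ks] <- occ_bone[, , ks, drop = FALSE] +
        array(as.numeric(b), c(dims[1], dims[2], length(ks)))
    }
  }
  hu <- hu / nsub
  occ_bone <- occ_bone / nsub

  if (spec$noise_sd > 0) {
    hu <- hu + with_seed(spec$seed, array(stats::rnorm(prod(dims), 0,
                                                       spec$noise_sd), dims))
  }
  volume <- ct_volume(hu, spacing = sp, origin = origin)

  # analytic-occupancy bone surface (marching tetrahedra on the partial
  # volume fraction field)
  res <- .marching_tets_cpp(as.numeric(occ_bone), dims, 0.5, rep(sp, 3),
                            origin)
  bone_surface <- drop_tiny_faces(surface_mesh(res$vertices, res$faces))

  fragment_surface <- NULL
  frag_axis <- NULL
  fp <- spec$fragment_pose
  if (!is.null(fp)) {
    d <- fp$direction / sqrt(sum(fp$direction^2))
    cyl <- revolve_profile(c(fp$diameter / 2, fp$diameter / 2),
                           c(0, fp$length), 32)
    pose <- rigid_transform(rotation_z_to(d), fp$point)
    fragment_surface <- transform_mesh(cyl, pose)
    frag_axis <- line3d(fp$point, d)
  }

  plans <- phantom_default_plans(spec)
  axes <- lapply(plans, function(p) line3d(p$entry, p$direction))
  if (!is.null(frag_axis)) axes$fragment <- frag_axis

  truth <- structure(list(
    spec = spec,
    true_hu_to_density = spec$hu_to_density,
    true_surfaces = list(bone = bone_surface, fragment = fragment_surface),
    true_axes = axes,
    plans = plans,
    landmarks = phantom_landmarks(spec),
    rods = phantom_rods(spec),
    true_density_field = occ_bone,  # bone partial-volume fraction per voxel
    origin = origin, spacing = sp, dims = dims), class = "phantom_truth")
  list(volume = volume, truth = truth)
}

phantom_bbox <- function(spec) {
  bs <- spec$bone_shape
  lo <- bs$body_center - bs$body_semi
  hi <- bs$body_center + bs$body_semi
  if (!is.null(bs$ala_center)) {
    lo <- pmin(lo, bs$ala_center - bs$ala_semi)
    hi <- pmax(hi, bs$ala_center + bs$ala_semi)
  }
  rods <- phantom_rods(spec)
  if (!is.null(rods)) {
    rlo <- apply(rods$centers, 2, min) - rods$radius
    rhi <- apply(rods$centers, 2, max) + rods$radius
    rlo[rods$axis] <- min(rods$centers[, rods$axis]) - rods$half_length
    rhi[rods$axis] <- max(rods$centers[, rods$axis]) + rods$half_length
    lo <- pmin(lo, rlo); hi <- pmax(hi, rhi)
  }
  list(lo = lo - spec$margin, hi = hi + spec$margin)
}

# run code under a local RNG seed without disturbing the global stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default surgical plans for the phantom
#'
#' Two screw trajectories analogous to the clinical scenario: a convergent
#' bicortical corridor through the body ("S1") and a divergent monocortical
#' corridor into the ala ("ALA"). Entry points are found exactly on the
#' analytic bone surface by bisection along the planned axes.
#'
#' @param spec A [phantom_spec()].
#' @param screw A [screw_spec()] (scaled with the phantom).
#' @return Named list of [trajectory_plan()] objects.
#' @export
phantom_default_plans <- function(spec, screw = NULL) {
  sc <- spec$scale
  if (is.null(screw))
    screw <- screw_spec(length = 45 * sc, diameter = 6.5 * sc,
                        head_diameter = 10 * sc, head_height = 9 * sc,
                        head_offset = 8 * sc)
  bs <- spec$bone_shape
  # convergent corridor runs just beneath the endplate (subchondral purchase)
  d1 <- c(-0.9, -0.5, 0); d1 <- d1 / sqrt(sum(d1^2))
  a1 <- bs$body_center + c(-8, 0, 5) * sc
  e1 <- phantom_surface_point(spec, a1, -d1)
  p1 <- trajectory_plan("S1", e1, d1, screw)
  plans <- list(S1 = p1)
  if (!is.null(bs$ala_center)) {
    # divergent corridor: enters the dorsolateral ala surface and runs
    # almost entirely within the marrow-soft ala wing
    d2 <- c(0.95, -0.31, 0); d2 <- d2 / sqrt(sum(d2^2))
    a2 <- bs$body_center + c(21, 13, 2) * sc
    e2 <- phantom_surface_point(spec, a2, -d2)
    plans$ALA <- trajectory_plan("ALA", e2, d2, screw)
  }
  plans
}

# six registration landmarks on the caudal bone surface, found analytically
phantom_landmarks <- function(spec) {
  bs <- spec$bone_shape
  anchor <- bs$body_center + c(0, 0, -0.5 * bs$body_semi[3])
  dirs <- rbind(c(0, 0, -1), c(0.8, 0.3, -0.6), c(-0.8, 0.3, -0.6),
                c(0.8, -0.3, -0.6), c(-0.8, -0.3, -0.6), c(0, 0.9, -0.45))
  t(apply(dirs, 1, function(d) phantom_surface_point(spec, anchor, d)))
}

#' Simulate a post-drill CT of the physical bone model
#'
#' Renders the bone solid (homogeneous plastic-like HU) with metal drill
#' bits along the realized axes, the whole scene moved by `applied_pose` —
#' the test bench for the accuracy-evaluation instrument. Registration
#' landmarks (moved with the scene) are attached for the landmark stage.
#'
#' @param truth A `phantom_truth`.
#' @param realized_axes Named list of [line3d()] realized drill axes in the
#'   plan frame (names matching the plan labels).
#' @param applied_pose A [rigid_transform()] applied to the whole scene.
#' @param bit_diameter Drill bit diameter, mm.
#' @param bit_protrusion,bit_depth Bit extent outside/inside the entry along
#'   the axis, mm.
#' @param model_hu Rendered HU of the printed bone model.
#' @return A [ct_volume()] with an attached `landmarks` element (list with
#'   `post` and `plan` matrices).
#' @export
simulate_postdrill_volume <- function(truth, realized_axes, applied_pose,
                                      bit_diameter = 2.5,
                                      bit_protrusion = 20, bit_depth = 35,
                                      model_hu = 700) {
  spec <- truth$spec
  for (nm in names(realized_axes)) {
    ln <- realized_axes[[nm]]
    hits <- phantom_axis_hits_bone(spec, ln)
    if (!hits) stop(sprintf("realized axis '%s' does not intersect the bone", nm))
  }
  inv_pose <- invert_transform(applied_pose)
  # scene bbox: transformed bone bbox + bits
  bb <- phantom_bbox(spec)
  corners <- as.matrix(expand.grid(c(bb$lo[1], bb$hi[1]),
                                   c(bb$lo[2], bb$hi[2]),
                                   c(bb$lo[3], bb$hi[3])))
  tc <- transform_points(applied_pose, corners)
  lo <- apply(tc, 2, min) - 4
  hi <- apply(tc, 2, max) + 4
  sp <- spec$voxel_spacing
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * sp)

  # bits as segments in the plan frame, then moved by the pose
  bits <- lapply(realized_axes, function(ln) {
    ent <- closest_axis_entry(spec, ln)
    list(base = ent - bit_protrusion * ln$direction,
         dir = ln$direction, len = bit_protrusion + bit_depth)
  })

  ss <- spec$supersample
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss * sp
  hu <- array(0, dims)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    for (k0 in seq(1, dims[3], by = 16)) {
      ks <- k0:min(k0 + 15, dims[3])
      pts <- as.matrix(expand.grid(x = ax[[1]] + ox, y = ax[[2]] + oy,
                                   z = ax[[3]][ks] + oz))
      pp <- transform_points(inv_pose, pts)  # back to plan frame
      h <- rep(-1000, nrow(pts))             # air around the printed model
      h[phantom_bone_level(spec, pp) <= 0] <- model_hu
      for (b in bits) {
        sel <- inside_cylinder(pp, b$base, b$dir, b$len, bit_diameter / 2)
        h[sel] <- spec$metal_hu
      }
      hu[, , ks] <- hu[, , ks, drop = FALSE] + array(h, c(dims[1], dims[2], length(ks)))
    }
  }
  hu <- hu / ss^3
  vol <- ct_volume(hu, spacing = sp, origin = lo)
  vol$landmarks <- list(post = transform_points(applied_pose, truth$landmarks),
                        plan = truth$landmarks)
  vol
}

phantom_axis_hits_bone <- function(spec, ln) {
  t <- seq(-60, 60, by = 0.5)
  pts <- outer(t, ln$direction) + matrix(ln$point, length(t), 3, byrow = TRUE)
  any(phantom_bone_level(spec, pts) <= 0)
}

# entry point of an axis into the bone (smallest-t surface crossing)
closest_axis_entry <- function(spec, ln) {
  t <- seq(-60, 60, by = 0.25)
  pts <- outer(t, ln$direction) + matrix(ln$point, length(t), 3, byrow = TRUE)
  inside <- phantom_bone_level(spec, pts) <= 0
  first <- which(inside)[1]
  if (is.na(first)) stop("axis does not intersect the bone")
  if (first == 1) return(pts[1, ])
  phantom_surface_point(spec, pts[min(which(inside)) + 2, ],
                        -ln$direction)
}
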