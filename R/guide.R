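#' Drill-guide template specification
#'
#' @param tube_inner_diameter Inner tube diameter (drill bit + clearance),
#'   mm.
#' @param tube_outer_diameter Outer tube diameter, mm.
#' @param tube_length Guide tube length, mm.
#' @param shell_thickness Contact-shell thickness, mm (> 0).
#' @param standoff Tube start above the bone entry along the axis, mm.
#' @export
guide_spec <- function(tube_inner_diameter = 2.7, tube_outer_diameter = 7,
                       tube_length = 18, shell_thickness = 3,
                       standoff = 0) {
  stopifnot(tube_inner_diameter > 0,
            tube_outer_diameter > tube_inner_diameter,
            tube_length > 0)
  if (shell_thickness <= 0) stop("shell_thickness must be > 0")
  structure(list(tube_inner_diameter = tube_inner_diameter,
                 tube_outer_diameter = tube_outer_diameter,
                 tube_length = tube_length,
                 shell_thickness = shell_thickness,
                 standoff = standoff),
            class = "guide_spec")
}

#' Extract the template/bone contact patch
#'
#' Selects the open surface patch the template will rest on: faces whose
#' outward normal points along `direction` (within `max_normal_angle_deg`)
#' and whose centroid lies inside the spatial `window`; the largest
#' connected patch is returned.
#'
#' @param bone Bone [surface_mesh()].
#' @param region List: `direction` (outward selection direction, e.g. dorsal
#'   `c(0, 1, 0)`), `max_normal_angle_deg` (default 60), and optional `xlim`,
#'   `ylim`, `zlim` windows (mm).
#' @return An open [surface_mesh()] patch (single connected component).
#' @export
extract_contact_patch <- function(bone, region) {
  dirv <- region$direction / sqrt(sum(region$direction^2))
  maxang <- region$max_normal_angle_deg %||% 60
  n <- mesh_face_normals(bone)
  keep <- as.numeric(n %*% dirv) >= cos(maxang * pi / 180)
  cent <- (bone$vertices[bone$faces[, 1], ] + bone$vertices[bone$faces[, 2], ] +
           bone$vertices[bone$faces[, 3], ]) / 3
  for (a in 1:3) {
    lim <- region[[c("xlim", "ylim", "zlim")[a]]]
    if (!is.null(lim)) keep <- keep & cent[, a] >= lim[1] & cent[, a] <= lim[2]
  }
  if (!any(keep)) stop("contact-patch selector matches no faces")
  sub <- surface_mesh(bone$vertices, bone$faces[keep, , drop = FALSE])
  comp <- mesh_components(sub)
  main <- which.max(tabulate(comp))
  sub <- surface_mesh(sub$vertices, sub$faces[comp == main, , drop = FALSE])
  used <- sort(unique(as.vector(sub$faces)))
  remap <- integer(nrow(sub$vertices)); remap[used] <- seq_along(used)
  surface_mesh(sub$vertices[used, , drop = FALSE],
               matrix(remap[sub$faces], ncol = 3))
}

#' Build the drill-guide template solid
#'
#' Implicit-solid construction: the union of (i) an offset shell of the
#' contact patch (grown outward along the patch normals to `shell_thickness`)
#' and (ii) one hollow tube per plan, coaxial with the planned axis, minus
#' the open drill channels. The combined implicit function is contoured by
#' marching tetrahedra into a watertight, printable surface; by construction
#' the tube axes equal the plan axes.
#'
#' @param patch Contact patch from [extract_contact_patch()].
#' @param plans List of [trajectory_plan()] objects whose axes pass within
#'   the patch footprint.
#' @param spec A [guide_spec()].
#' @param resolution Contouring grid pitch, mm.
#' @return A watertight [surface_mesh()] with attribute `plans` recording the
#'   axes.
#' @export
build_guide <- function(patch, plans, spec, resolution = 0.5) {
  stopifnot(inherits(spec, "guide_spec"))
  # light smoothing removes contouring aliasing from image-derived patches
  # (boundary vertices stay fixed), which keeps the offset shell clean
  patch <- suppressWarnings(smooth_surface(patch, iterations = 3,
                                           factor = 0.6))

  # tube segments along each plan axis, starting at the entry point
  tubes <- lapply(plans, function(pl) {
    d_out <- -pl$direction   # outward
    ent <- pl$entry
    hit <- closest_point_on_mesh(matrix(ent, 1, 3), patch)
    if (hit$distance > spec$tube_outer_diameter + spec$shell_thickness + 2)
      stop(sprintf("plan '%s' axis misses the contact patch footprint",
                   pl$label))
    list(base = ent + spec$standoff * d_out, dir = d_out,
         len = spec$tube_length)
  })

  # implicit field: positive inside the guide solid
  lo <- apply(patch$vertices, 2, min)
  hi <- apply(patch$vertices, 2, max)
  for (tb in tubes) {
    ends <- rbind(tb$base, tb$base + tb$len * tb$dir)
    lo <- pmin(lo, apply(ends, 2, min) - spec$tube_outer_diameter / 2)
    hi <- pmax(hi, apply(ends, 2, max) + spec$tube_outer_diameter / 2)
  }
  pad <- spec$shell_thickness + 1 + 2 * resolution
  lo <- lo - pad; hi <- hi + pad
  dims <- as.integer(ceiling((hi - lo) / resolution)) + 1L
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * resolution)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))

  cp <- closest_point_on_mesh(pts, patch,
                              max_dist = spec$shell_thickness + 2)
  found <- is.finite(cp$distance) & cp$face > 0
  # signed offset along the patch normal (positive = outward of the bone)
  fn <- mesh_face_normals(patch)
  g_shell <- rep(-1, nrow(pts))
  if (any(found)) {
    s <- rowSums((pts[found, , drop = FALSE] - cp$point[found, , drop = FALSE]) *
                   fn[cp$face[found], , drop = FALSE])
    lateral <- sqrt(pmax(cp$distance[found]^2 - s^2, 0))
    # shell slab: 0..thickness outward of the patch, within its footprint
    g_shell[found] <- pmin(s, spec$shell_thickness - s, 1 - lateral)
  }
  g <- g_shell
  for (tb in tubes) {
    rel <- sweep(pts, 2, tb$base)
    t_ax <- as.numeric(rel %*% tb$dir)
    r_ax <- sqrt(pmax(rowSums(rel^2) - t_ax^2, 0))
    g_tube <- pmin(spec$tube_outer_diameter / 2 - r_ax, t_ax, tb$len - t_ax)
    g <- pmax(g, g_tube)
  }
  # drill channels: subtract open cylinders (axially unbounded)
  for (tb in tubes) {
    rel <- sweep(pts, 2, tb$base)
    t_ax <- as.numeric(rel %*% tb$dir)
    r_ax <- sqrt(pmax(rowSums(rel^2) - t_ax^2, 0))
    g <- pmin(g, r_ax - spec$tube_inner_diameter / 2)
  }

  res <- .marching_tets_cpp(as.numeric(g), dims, 0, rep(resolution, 3), lo)
  mesh <- drop_tiny_faces(surface_mesh(res$vertices, res$faces))
  comp <- mesh_components(mesh)
  if (max(comp) > 1) {  # keep the main solid (stray slivers possible)
    main <- which.max(tabulate(comp))
    mesh <- surface_mesh(mesh$vertices, mesh$faces[comp == main, , drop = FALSE])
    used <- sort(unique(as.vector(mesh$faces)))
    remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
    mesh <- surface_mesh(mesh$vertices[used, , drop = FALSE],
                         matrix(remap[mesh$faces], ncol = 3))
  }
  if (!is_watertight(mesh)) stop("guide solid is not watertight")
  attr(mesh, "plans") <- lapply(plans, function(pl)
    line3d(pl$entry, pl$direction))
  mesh
}

#' Genus of a closed connected mesh
#'
#' From the Euler characteristic `V - E + F = 2 - 2g`. A guide with two
#' through-tubes has genus 2.
#' @param mesh A watertight connected [surface_mesh()].
#' @export
mesh_genus <- function(mesh) {
  v <- nrow(mesh$vertices)
  f <- nrow(mesh$faces)
  e <- nrow(mesh_edge_table(mesh$faces))
  (2 - (v - e + f)) / 2
}

#' Part comparison: signed distance map between two meshes
#'
#' For each vertex of `meshA`, the signed distance to `meshB` (negative
#' inside B, by B's outward normals), as used to compare a cast part with
#' its printed pattern. Values are summarised and additionally clipped to
#' `clip` for rendering parity with part-comparison colour maps.
#'
#' @param meshA,meshB Pre-aligned [surface_mesh()] objects.
#' @param clip Colour-scale clip range, mm.
#' @return List: `signed_distance` per vertex of A, `clipped`, and `stats`
#'   (mean, RMS, p95 of |d|, max |d|).
#' @export
compare_cast_to_pattern <- function(meshA, meshB, clip = c(-1, 1)) {
  cp <- closest_point_on_mesh(meshA$vertices, meshB)
  fn <- mesh_face_normals(meshB)
  s <- rowSums((meshA$vertices - cp$point) * fn[cp$face, , drop = FALSE])
  d <- sign(ifelse(s == 0, 1, s)) * cp$distance
  list(signed_distance = d,
       clipped = pmin(pmax(d, clip[1]), clip[2]),
       stats = list(mean = mean(d), rms = sqrt(mean(d^2)),
                    p95_abs = as.numeric(stats::quantile(abs(d), 0.95)),
                    max_abs = max(abs(d))))
}
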