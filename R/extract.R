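#' Extract a triangulated surface from a mask
#'
#' Marching-tetrahedra isosurface of the (optionally pre-smoothed) binary
#' mask at level 0.5, in mm coordinates (voxel centre of 0-based index `i`
#' maps to `origin + i * spacing`). The binary mask is first averaged with a
#' 3x3x3 box kernel (`presmooth` passes) so the 0.5-level set tracks the
#' partial-volume boundary instead of the voxel staircase; the output is
#' closed and oriented outward.
#'
#' @param mask A `ct_mask` (from [segment()]) or a list with `mask`,
#'   `spacing`, `origin`.
#' @param presmooth Number of box-filter passes applied to the indicator
#'   field before contouring (0 = raw binary staircase).
#' @return A watertight [surface_mesh()].
#' @export
extract_surface <- function(mask, presmooth = 1) {
  m <- mask$mask
  if (!any(m)) stop("empty mask")
  field <- array(as.numeric(m), dim(m))
  for (i in seq_len(presmooth)) field <- box_filter3(field)
  res <- .marching_tets_cpp(as.numeric(field), dim(field), 0.5,
                            mask$spacing, mask$origin)
  mesh <- surface_mesh(res$vertices, res$faces)
  drop_tiny_faces(mesh)
}

# 3x3x3 box filter with zero (background) padding
box_filter3 <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs - dx, ys - dy, zs - dz] <- out[xs - dx, ys - dy, zs - dz] +
      a[xs, ys, zs]
  }
  out / 27
}

# weld near-coincident marching-tets vertices and drop zero-area slivers
drop_tiny_faces <- function(mesh, tol = 1e-9) {
  mesh <- weld_vertices(mesh, tol = 1e-7)
  areas <- mesh_face_areas(mesh)
  if (any(areas <= tol)) {
    # collapsing exact slivers would open the mesh; keep them unless truly zero
    keep <- areas > 0
    mesh <- surface_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
  }
  mesh
}

#' Taubin surface smoothing with shrinkage compensation
#'
#' Two-pass lambda/mu Taubin smoothing: each iteration applies a positive
#' Laplacian step (weight `factor`) followed by a negative step
#' (`mu = -factor / (1 - 0.1 * factor)`) that re-inflates the surface, so
#' the enclosed volume is nearly preserved (the "shrinkage compensation").
#' Boundary vertices of open meshes are kept fixed.
#'
#' @param mesh A [surface_mesh()].
#' @param iterations Number of smoothing iterations (>= 0).
#' @param factor Positive smoothing weight in (0, 1).
#' @return The smoothed [surface_mesh()]. If the input is open, a warning is
#'   issued (enclosed-volume bookkeeping is undefined for open meshes).
#' @export
smooth_surface <- function(mesh, iterations = 6, factor = 0.7) {
  stopifnot(iterations >= 0, factor > 0, factor < 1)
  if (iterations == 0) return(mesh)
  open_mesh <- !is_watertight(mesh)
  if (open_mesh)
    warning("mesh is open; boundary held fixed and volume check not applicable")
  V <- mesh$vertices
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  deg <- tabulate(e[, 1], nbins = nrow(V))
  movable <- deg > 0
  if (open_mesh) {
    et <- mesh_edge_table(F)
    bnd <- unique(c(et$v1[et$count == 1], et$v2[et$count == 1]))
    movable[bnd] <- FALSE
  }
  mu <- -factor / (1 - 0.1 * factor)
  step <- function(V, w) {
    nb <- rowsum(V[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
    ids <- as.integer(rownames(nb))
    lap <- nb / deg[ids] - V[ids, , drop = FALSE]
    upd <- movable[ids]
    V[ids[upd], ] <- V[ids[upd], , drop = FALSE] + w * lap[upd, , drop = FALSE]
    V
  }
  for (it in seq_len(iterations)) {
    V <- step(V, factor)
    V <- step(V, mu)
  }
  surface_mesh(V, F)
}
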