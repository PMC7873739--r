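#' Triangulated surface mesh
#'
#' @param vertices n x 3 matrix of mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of bounds")
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen)) stop("degenerate faces (repeated vertex index)")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  wt <- is_watertight(x)
  cat(if (wt) ", watertight" else ", open", "\n")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Axis-aligned box mesh
#'
#' Minimal 12-triangle watertight box, outward oriented — handy as a sharp-
#' edged test solid.
#' @param lo,hi Opposite corners, mm.
#' @return A [surface_mesh()].
#' @export
make_box <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  V <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  # vertex order: x fastest (1..8 per bit pattern x+2y+4z)
  quads <- rbind(c(1, 3, 4, 2), c(5, 6, 8, 7),   # z- (down), z+ (up)
                 c(1, 2, 6, 5), c(3, 7, 8, 4),   # y-, y+
                 c(1, 5, 7, 3), c(2, 4, 8, 6))   # x-, x+
  F <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  m <- surface_mesh(V, F)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Per-face areas of a mesh
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of triangle areas, mm^2.
#' @export
mesh_face_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area
#' @param mesh A [surface_mesh()].
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' Enclosed volume of a closed oriented mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed surfaces.
#' @param mesh A [surface_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Per-face unit normals
#' @param mesh A [surface_mesh()].
#' @return m x 3 matrix of outward unit normals (for consistently oriented
#'   meshes).
#' @export
mesh_face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Area-weighted per-vertex unit normals
#' @param mesh A [surface_mesh()].
#' @export
mesh_vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])  # area-weighted (un-normalised)
  vn <- matrix(0, nrow(V), 3)
  for (c_ in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(n[, k], F[, c_], reorder = FALSE)
      vn[as.integer(rownames(acc)), k] <- vn[as.integer(rownames(acc)), k] + acc
    }
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

# undirected edge table: one row per unique edge, with counts
mesh_edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  data.frame(v1 = pmin(e[first, 1], e[first, 2]),
             v2 = pmax(e[first, 1], e[first, 2]),
             count = as.integer(tab[key[first]]))
}

#' Is a mesh watertight?
#'
#' Checks that every undirected edge is shared by exactly two faces and that
#' each directed half-edge occurs exactly once (consistent orientation).
#' @param mesh A [surface_mesh()].
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  F <- mesh$faces
  et <- mesh_edge_table(F)
  if (any(et$count != 2)) return(FALSE)
  dir_key <- c(paste(F[, 1], F[, 2]), paste(F[, 2], F[, 3]), paste(F[, 3], F[, 1]))
  !anyDuplicated(dir_key)
}

#' Connected components of a mesh
#'
#' Components over faces sharing vertices (union-find).
#' @param mesh A [surface_mesh()].
#' @return Integer vector: component id per face, ids 1..n_components.
#' @export
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  F <- mesh$faces
  for (r in seq_len(nrow(F))) {
    a <- find(F[r, 1]); b <- find(F[r, 2]); c_ <- find(F[r, 3])
    parent[b] <- a; parent[find(c_)] <- a
  }
  roots <- vapply(F[, 1], find, integer(1))
  as.integer(factor(roots))
}

#' Transform a mesh by a rigid transform
#' @param mesh A [surface_mesh()].
#' @param transform A [rigid_transform()].
#' @export
transform_mesh <- function(mesh, transform) {
  surface_mesh(transform_points(transform, mesh$vertices), mesh$faces)
}

#' Merge duplicate vertices
#'
#' Welds vertices closer than `tol` (exact grid snap), dropping faces that
#' become degenerate.
#' @param mesh A [surface_mesh()].
#' @param tol Welding tolerance, mm.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  key <- apply(round(mesh$vertices / tol), 1, paste, collapse = ",")
  map <- match(key, key[!duplicated(key)])
  V <- mesh$vertices[!duplicated(key), , drop = FALSE]
  F <- matrix(map[mesh$faces], ncol = 3)
  keep <- F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3]
  surface_mesh(V, F[keep, , drop = FALSE])
}

#' Points-in-mesh test
#'
#' Even-odd ray-parity containment test against a closed mesh.
#' @param points n x 3 matrix of query points, mm.
#' @param mesh A closed [surface_mesh()].
#' @return Logical vector.
#' @export
points_in_mesh <- function(points, mesh) {
  .points_in_mesh_cpp(as.matrix(points), mesh$vertices, mesh$faces)
}

#' Closest points on a mesh
#'
#' @param points n x 3 query points, mm.
#' @param mesh A [surface_mesh()].
#' @return List with `distance` (mm), `point` (n x 3 closest points) and
#'   `face` (1-based triangle index).
#' @export
closest_point_on_mesh <- function(points, mesh, max_dist = Inf) {
  .closest_point_mesh_cpp(as.matrix(points), mesh$vertices, mesh$faces,
                          max_dist)
}

#' Line-mesh intersection parameters
#'
#' All intersections of the infinite line `origin + t * direction` with the
#' mesh, as sorted `t` values (mm if `direction` is unit length).
#' @param origin,direction Line origin and direction.
#' @param mesh A [surface_mesh()].
#' @export
line_mesh_intersections <- function(origin, direction, mesh, tol = 1e-6) {
  hits <- .ray_mesh_hits_cpp(as.numeric(origin), as.numeric(direction),
                             mesh$vertices, mesh$faces)
  # a crossing through a shared edge/vertex is reported by both incident
  # triangles; merge coincident parameters
  if (length(hits) > 1) hits <- hits[c(TRUE, diff(hits) > tol)]
  hits
}
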