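#' Quadratic tetrahedral mesh of a bone/implant assembly
#'
#' Structured voxel-grid tet10 mesher: a uniform node lattice at spacing
#' `max_edge_bone` is laid over the assembly, each grid cell is split into
#' the six Kuhn tetrahedra sharing the cell's main diagonal, and each
#' tetrahedron is labelled `screw` / `fragment` / `bone` by a containment
#' test of its centroid against the assembly surfaces (screw taking
#' precedence where solids overlap). Screw and bone elements share lattice
#' nodes at the interface, which realises the tied (fully bonded) interface
#' kinematics directly. Midside nodes sit at edge midpoints (straight-edged
#' elements).
#'
#' @param assy An [assembly()] with at least one placed screw.
#' @param max_edge_bone Lattice spacing = element edge scale, mm.
#' @param edge_interface Supersampling scale for labelling near interfaces:
#'   tetrahedra whose centroid test is ambiguous at coarse size are labelled
#'   by majority over subsamples at this pitch, mm.
#' @return A `tet_mesh`: `nodes` (n x 3 mm), `elements` (m x 10, C3D10 corner
#'   + midside ordering), `part` (factor), `E`/`nu` (NA until material
#'   assignment), plus lattice metadata.
#' @export
tetrahedralize <- function(assy, max_edge_bone, edge_interface = 0.6) {
  stopifnot(max_edge_bone > 0)
  h <- max_edge_bone
  solids <- c(list(bone = assy$bone),
              if (!is.null(assy$fragment)) list(fragment = assy$fragment),
              assy$screws)
  # lattice aligned to the assembly bbox so axis-aligned solids mesh exactly
  bbs <- lapply(solids, function(m) apply(m$vertices, 2, range))
  lo <- do.call(pmin, lapply(bbs, function(b) b[1, ]))
  hi <- do.call(pmax, lapply(bbs, function(b) b[2, ])) + 1e-9
  nd <- pmax(2L, as.integer(ceiling((hi - lo) / h)) + 1L)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(nd[a]) - 1) * h)

  # cell bases (1-based corner index of each cell)
  nc <- nd - 1L
  cell_ijk <- as.matrix(expand.grid(i = seq_len(nc[1]), j = seq_len(nc[2]),
                                    k = seq_len(nc[3])))
  node_id <- function(i, j, k) i + nd[1] * ((j - 1L) + nd[2] * (k - 1L))
  corner_bits <- cbind(x = bitwAnd(0:7, 1L),
                       y = bitwAnd(bitwShiftR(0:7, 1L), 1L),
                       z = bitwAnd(bitwShiftR(0:7, 2L), 1L))
  kuhn <- rbind(c(0, 1, 3, 7), c(0, 1, 5, 7), c(0, 2, 3, 7),
                c(0, 2, 6, 7), c(0, 4, 5, 7), c(0, 4, 6, 7)) + 1L

  # fix orientation per tet type on the unit cell (positive volume)
  unit <- corner_bits
  for (t in 1:6) {
    c4 <- unit[kuhn[t, ], ]
    v <- det(cbind(c4[2, ] - c4[1, ], c4[3, ] - c4[1, ], c4[4, ] - c4[1, ]))
    if (v < 0) kuhn[t, ] <- kuhn[t, c(1, 3, 2, 4)]
  }

  base_xyz <- cbind(ax[[1]][cell_ijk[, 1]], ax[[2]][cell_ijk[, 2]],
                    ax[[3]][cell_ijk[, 3]])
  ncell <- nrow(cell_ijk)

  # centroid per tet type (offset within cell), containment per solid
  labels <- matrix(NA_character_, ncell, 6)
  inbone <- matrix(FALSE, ncell, 6)
  for (t in 1:6) {
    off <- colMeans(unit[kuhn[t, ], ]) * h
    cent <- sweep(base_xyz, 2, off, `+`)
    lab <- rep(NA_character_, ncell)
    for (nm in names(solids)) {  # bone first; fragment, then screws override
      inside <- points_in_mesh(cent, solids[[nm]])
      lab[inside] <- nm
      if (nm == "bone") inbone[, t] <- inside
    }
    labels[, t] <- lab
  }

  keep <- which(!is.na(labels))
  if (length(keep) == 0) stop("no element centroid falls inside any solid")
  tet_of <- ((keep - 1L) %/% ncell) + 1L   # tet type
  cell_of <- ((keep - 1L) %% ncell) + 1L

  # corner node ids per kept tet
  elems4 <- matrix(0L, length(keep), 4)
  for (c_ in 1:4) {
    bit <- corner_bits[kuhn[cbind(tet_of, c_)], , drop = FALSE]
    elems4[, c_] <- node_id(cell_ijk[cell_of, 1] + bit[, 1],
                            cell_ijk[cell_of, 2] + bit[, 2],
                            cell_ijk[cell_of, 3] + bit[, 3])
  }

  # compact corner nodes
  used <- sort(unique(as.vector(elems4)))
  remap <- integer(prod(nd)); remap[used] <- seq_along(used)
  elems4 <- matrix(remap[elems4], ncol = 4)
  uijk <- arrayInd(used, nd)
  nodes <- cbind(ax[[1]][uijk[, 1]], ax[[2]][uijk[, 2]], ax[[3]][uijk[, 3]])

  # detach proud implant elements: an implant element whose centroid lies
  # outside the bone is not in (tied) contact with it, so it must not share
  # lattice nodes with bone/other-part elements — otherwise the staircase
  # welds the proud neck/head to the nearby cortex. Conflicting nodes are
  # duplicated for the proud side; the implant stays connected through its
  # own embedded elements.
  part_chr <- labels[keep]
  emb <- inbone[keep]
  for (nm in setdiff(unique(part_chr), "bone")) {
    rows_part <- part_chr == nm
    proud_rows <- rows_part & !emb
    if (!any(proud_rows)) next
    other_nodes <- unique(as.vector(elems4[!rows_part, , drop = FALSE]))
    embed_nodes <- unique(as.vector(elems4[rows_part & emb, , drop = FALSE]))
    conflict <- setdiff(intersect(
      unique(as.vector(elems4[proud_rows, , drop = FALSE])), other_nodes),
      embed_nodes)
    if (length(conflict) == 0) next
    dup_map <- integer(nrow(nodes))
    dup_map[conflict] <- nrow(nodes) + seq_along(conflict)
    nodes <- rbind(nodes, nodes[conflict, , drop = FALSE])
    sub <- elems4[proud_rows, , drop = FALSE]
    hit <- dup_map[sub] > 0
    sub[hit] <- dup_map[sub][hit]
    elems4[proud_rows, ] <- sub
  }

  # midside nodes on the 6 element edges (C3D10 order)
  edge_pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  nv <- nrow(nodes)
  mid_ids <- matrix(0L, nrow(elems4), 6)
  ekey_all <- NULL
  for (e in 1:6) {
    a <- elems4[, edge_pairs[e, 1]]; b <- elems4[, edge_pairs[e, 2]]
    ekey_all <- cbind(ekey_all, pmin(a, b) * (nv + 1) + pmax(a, b))
  }
  uk <- unique(as.vector(ekey_all))
  mid_index <- nv + match(as.vector(ekey_all), uk)
  mid_ids[] <- mid_index
  # integer recovery: key = a*(nv+1)+b with 1 <= b <= nv
  ua <- as.integer((uk - 1) %/% (nv + 1))
  ub <- as.integer(uk - as.numeric(ua) * (nv + 1))
  mids <- (nodes[ua, , drop = FALSE] + nodes[ub, , drop = FALSE]) / 2
  nodes <- rbind(nodes, mids)
  elements <- cbind(elems4, mid_ids)

  part <- factor(labels[keep],
                 levels = unique(c("bone", "fragment",
                                   setdiff(names(solids), c("bone", "fragment")))))
  structure(list(nodes = nodes, elements = elements, part = part,
                 E = rep(NA_real_, nrow(elements)),
                 nu = rep(NA_real_, nrow(elements)),
                 h = h, lattice_origin = lo, lattice_dims = nd,
                 edge_interface = edge_interface,
                 elem_key = paste0(cell_of, "_", tet_of)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tet10 elements (h = %.2f mm)\n",
              nrow(x$nodes), nrow(x$elements), x$h))
  print(table(x$part))
  invisible(x)
}

#' Per-element volumes of a tet mesh
#' @param mesh A `tet_mesh`.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; el <- mesh$elements
  a <- n[el[, 2], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  b <- n[el[, 3], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  c_ <- n[el[, 4], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
   a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Assign heterogeneous material properties per element
#'
#' Bone elements receive `E` mapped from the mean HU of the CT voxels whose
#' centres fall inside the element (metal-HU voxels excluded so an adjacent
#' implant does not inflate bone stiffness); elements containing no voxel
#' centre fall back to trilinear interpolation of HU at the element centroid.
#' Implant elements (screws, fragment) get the titanium-alloy constants
#' E = 114000 MPa, nu = 0.3 regardless of the image.
#'
#' @param mesh A `tet_mesh` from [tetrahedralize()].
#' @param volume The calibrated [ct_volume()].
#' @param model A [density_modulus_model()].
#' @param metal_hu Metal exclusion threshold, HU.
#' @param implant_e,implant_nu Implant constants.
#' @param sampling `"mean"` (voxel mean, default) or `"centroid"`
#'   (interpolated HU at the centroid only).
#' @return The mesh with `E`, `nu` and a `material_report` data.frame
#'   attached.
#' @export
assign_element_materials <- function(mesh, volume, model,
                                     metal_hu = 2000,
                                     implant_e = 114000, implant_nu = 0.3,
                                     sampling = c("mean", "centroid")) {
  sampling <- match.arg(sampling)
  nel <- nrow(mesh$elements)
  el4 <- mesh$elements[, 1:4, drop = FALSE]
  is_bone <- mesh$part == "bone"

  # bounds check
  bb_lo <- volume$origin - volume$spacing / 2
  bb_hi <- volume$origin + (dim(volume$voxels) - 1) * volume$spacing +
    volume$spacing / 2
  # only bone elements sample the image; implants may protrude past it
  bone_nodes_idx <- unique(as.vector(el4[is_bone, , drop = FALSE]))
  if (length(bone_nodes_idx) > 0) {
    nr <- apply(mesh$nodes[bone_nodes_idx, , drop = FALSE], 2, range)
    if (any(nr[1, ] < bb_lo - 1e-9) || any(nr[2, ] > bb_hi + 1e-9))
      stop("bone mesh extends outside the volume bounds")
  }

  cent <- (mesh$nodes[el4[, 1], ] + mesh$nodes[el4[, 2], ] +
           mesh$nodes[el4[, 3], ] + mesh$nodes[el4[, 4], ]) / 4
  mean_hu <- rep(NA_real_, nel)

  if (sampling == "mean") {
    # map every non-metal voxel centre to its containing element:
    # voxel -> lattice cell -> Kuhn tet by coordinate ordering
    vc_idx <- which(volume$voxels < metal_hu)
    vc <- voxel_centers(volume, volume$voxels < metal_hu)
    hu <- volume$voxels[vc_idx]
    loc <- sweep(vc, 2, mesh$lattice_origin) / mesh$h
    cell <- floor(loc)
    frac <- loc - cell
    inb <- cell[, 1] >= 0 & cell[, 2] >= 0 & cell[, 3] >= 0 &
      cell[, 1] < mesh$lattice_dims[1] - 1 &
      cell[, 2] < mesh$lattice_dims[2] - 1 &
      cell[, 3] < mesh$lattice_dims[3] - 1
    cell <- cell[inb, , drop = FALSE]; frac <- frac[inb, , drop = FALSE]
    hu <- hu[inb]
    # Kuhn tet type from the ordering of fractional coordinates
    tet_type <- kuhn_type(frac)
    ckey <- cell_key(cell[, 1] + 1L, cell[, 2] + 1L, cell[, 3] + 1L,
                     tet_type, mesh$lattice_dims)
    sums <- rowsum(hu, ckey, reorder = FALSE)
    cnts <- rowsum(rep(1, length(hu)), ckey, reorder = FALSE)
    mt <- match(mesh$elem_key, rownames(sums))
    got <- !is.na(mt)
    mean_hu[got] <- sums[mt[got], 1] / cnts[mt[got], 1]
  }
  need_interp <- is.na(mean_hu) & is_bone
  if (any(need_interp))
    # metal exclusion also applies to the centroid fallback: an interpolated
    # value reaching into implant HU is clamped below the metal threshold
    mean_hu[need_interp] <- pmin(
      interp_hu(volume, cent[need_interp, , drop = FALSE]), metal_hu - 1)

  E <- rep(implant_e, nel)
  nu <- rep(implant_nu, nel)
  rho <- rep(NA_real_, nel)
  clamped <- rep(FALSE, nel)
  if (any(is_bone)) {
    rho_b <- law_eval(model$hu_to_density, mean_hu[is_bone])
    e_b <- density_to_modulus(model, rho_b)
    E[is_bone] <- e_b
    nu[is_bone] <- model$poisson
    rho[is_bone] <- rho_b
    clamped[is_bone] <- attr(e_b, "clamped")
  }
  mesh$E <- as.numeric(E)
  mesh$nu <- nu
  mesh$material_report <- data.frame(
    element = seq_len(nel), part = as.character(mesh$part),
    mean_hu = mean_hu, rho_app = rho, E_mpa = as.numeric(E),
    clamped = clamped)
  mesh
}

# which of the 6 Kuhn tets (ordering of fractional coords) a point is in;
# must match the decomposition used by tetrahedralize
kuhn_type <- function(frac) {
  x <- frac[, 1]; y <- frac[, 2]; z <- frac[, 3]
  # permutation regions: xyz:{x>=y>=z}, xzy:{x>=z>=y}, yxz:{y>=x>=z},
  # yzx:{y>=z>=x}, zxy:{z>=x>=y}, zyx:{z>=y>=x}
  type <- integer(length(x))
  type[x >= y & y >= z] <- 1L
  type[type == 0L & x >= z & z > y] <- 2L
  type[type == 0L & y > x & x >= z] <- 3L
  type[type == 0L & y >= z & z > x] <- 4L
  type[type == 0L & z > x & x >= y] <- 5L
  type[type == 0L & z >= y & y > x] <- 6L
  type
}

cell_key <- function(i, j, k, tet_type, nd) {
  cell_lin <- i + (nd[1] - 1) * ((j - 1) + (nd[2] - 1) * (k - 1))
  paste0(cell_lin, "_", tet_type)
}

# trilinear HU interpolation at arbitrary points
interp_hu <- function(volume, pts) {
  d <- dim(volume$voxels)
  loc <- sweep(sweep(pts, 2, volume$origin), 2, volume$spacing, `/`)
  i0 <- floor(loc)
  for (a in 1:3) i0[, a] <- pmin(pmax(i0[, a], 0), d[a] - 2)
  f <- loc - i0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
         (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
         (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    out <- out + w * volume$voxels[idx]
  }
  out
}
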