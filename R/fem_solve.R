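#' Boundary-condition node sets
#'
#' Resolves the fixed and loaded node sets of the pull-out load case: the
#' bone is fixed on the superior endplate patch and on the caudal third of
#' its axial extent; the tensile load acts on the screw head, and the mean
#' head displacement is measured over the nodes of the middle third of the
#' head's axial extent.
#'
#' @param mesh A `tet_mesh`.
#' @param endplate_region List with `depth` (mm below the bone's top, default
#'   3) and optionally `xlim`/`ylim` windows.
#' @param caudal_fraction Fraction of the bone axial (z) extent fixed from
#'   below, default 1/3.
#' @param head_spec List with `plan` (the [trajectory_plan()] of the loaded
#'   screw); the head band is derived from its screw geometry.
#' @return A `node_sets` list: `fixed_endplate`, `fixed_caudal`, `head_load`,
#'   `head_measure` (node index vectors).
#' @export
define_node_sets <- function(mesh, endplate_region = list(depth = 3),
                             caudal_fraction = 1 / 3, head_spec) {
  bone_el <- mesh$part == "bone"
  if (!any(bone_el)) stop("mesh has no bone elements")
  surf <- boundary_nodes(mesh)
  bone_nodes <- unique(as.vector(mesh$elements[bone_el, ]))
  bsurf <- intersect(surf, bone_nodes)
  z <- mesh$nodes[, 3]
  zr <- range(z[bone_nodes])
  caudal <- bsurf[z[bsurf] <= zr[1] + caudal_fraction * diff(zr) + 1e-9]
  depth <- endplate_region$depth %||% 3
  ep <- bsurf[z[bsurf] >= zr[2] - depth]
  if (!is.null(endplate_region$xlim))
    ep <- ep[mesh$nodes[ep, 1] >= endplate_region$xlim[1] &
             mesh$nodes[ep, 1] <= endplate_region$xlim[2]]
  if (!is.null(endplate_region$ylim))
    ep <- ep[mesh$nodes[ep, 2] >= endplate_region$ylim[1] &
             mesh$nodes[ep, 2] <= endplate_region$ylim[2]]

  plan <- head_spec$plan
  lab <- plan$label
  screw_el <- mesh$part == lab
  if (!any(screw_el)) stop(sprintf("mesh has no elements for screw '%s'", lab))
  snodes <- unique(as.vector(mesh$elements[screw_el, ]))
  L <- plan$screw$length; H <- plan$screw$head_height
  Lh <- L + (plan$screw$head_offset %||% 0)   # head starts above the neck
  tip <- plan$entry + L * plan$direction
  s <- as.matrix(mesh$nodes[snodes, , drop = FALSE]) %*% (-plan$direction) -
    sum(tip * (-plan$direction))
  head_all <- snodes[s >= Lh - 1e-6]
  head_measure <- snodes[s >= Lh + H / 3 - 1e-6 & s <= Lh + 2 * H / 3 + 1e-6]
  fixed <- union(caudal, ep)
  head_all <- setdiff(head_all, fixed)
  head_measure <- setdiff(head_measure, fixed)
  sets <- list(fixed_endplate = ep, fixed_caudal = caudal,
               head_load = head_all, head_measure = head_measure)
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0]
  if (length(empty) > 0)
    stop("empty node set(s): ", paste(empty, collapse = ", "))
  structure(sets, class = "node_sets")
}

# nodes on the exterior boundary of the tet mesh (corner + midside)
boundary_nodes <- function(mesh) {
  el <- mesh$elements
  faces_c <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                   el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  # matching midside nodes per face (C3D10: 5=12, 6=23, 7=13, 8=14, 9=24, 10=34)
  faces_m <- rbind(el[, c(5, 6, 7)], el[, c(5, 9, 8)],
                   el[, c(7, 10, 8)], el[, c(6, 10, 9)])
  key <- apply(t(apply(faces_c, 1, sort)), 1, paste, collapse = "_")
  once <- key %in% names(which(table(key) == 1))
  unique(c(as.vector(faces_c[once, ]), as.vector(faces_m[once, ])))
}

#' Consistent nodal forces for a uniform traction on boundary faces
#'
#' For quadratic tetrahedra, lumping a uniform surface traction equally over
#' face nodes is inconsistent; the consistent load vector of a straight
#' 6-node triangular face puts zero on the corners and one third of the face
#' force on each midside node. This helper builds that load for all exterior
#' boundary faces whose six nodes lie in `face_nodes`.
#'
#' @param mesh A `tet_mesh`.
#' @param face_nodes Node indices describing the loaded surface.
#' @param total_force Total force magnitude, N.
#' @param direction Unit force direction.
#' @return Dense dof force vector (length 3 * n_nodes).
#' @export
consistent_face_load <- function(mesh, face_nodes, total_force, direction) {
  el <- mesh$elements
  faces_c <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                   el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  faces_m <- rbind(el[, c(5, 6, 7)], el[, c(5, 9, 8)],
                   el[, c(7, 10, 8)], el[, c(6, 10, 9)])
  key <- apply(t(apply(faces_c, 1, sort)), 1, paste, collapse = "_")
  bnd <- key %in% names(which(table(key) == 1))
  sel <- bnd & (faces_c[, 1] %in% face_nodes) &
    (faces_c[, 2] %in% face_nodes) & (faces_c[, 3] %in% face_nodes) &
    (faces_m[, 1] %in% face_nodes) & (faces_m[, 2] %in% face_nodes) &
    (faces_m[, 3] %in% face_nodes)
  if (!any(sel)) stop("no boundary face lies entirely in face_nodes")
  fc <- faces_c[sel, , drop = FALSE]
  fm <- faces_m[sel, , drop = FALSE]
  v1 <- mesh$nodes[fc[, 2], , drop = FALSE] - mesh$nodes[fc[, 1], , drop = FALSE]
  v2 <- mesh$nodes[fc[, 3], , drop = FALSE] - mesh$nodes[fc[, 1], , drop = FALSE]
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  per_face <- total_force * area / sum(area)
  f <- numeric(3 * nrow(mesh$nodes))
  dirn <- direction / sqrt(sum(direction^2))
  for (k in 1:3) {
    contrib <- rowsum(rep(per_face / 3, 3) * dirn[k],
                      as.vector(fm), reorder = TRUE)
    ids <- as.integer(rownames(contrib))
    f[3 * (ids - 1) + k] <- f[3 * (ids - 1) + k] + contrib
  }
  f
}

#' Pull-out load case
#'
#' @param magnitude Total load, N (> 0, default 500).
#' @param direction Unit load direction; for a pull-out test this is the
#'   outward screw axis (minus the insertion direction).
#' @export
load_case <- function(magnitude = 500, direction) {
  stopifnot(magnitude > 0)
  nrm <- sqrt(sum(direction^2))
  structure(list(magnitude = magnitude, direction = direction / nrm),
            class = "load_case")
}

#' Static linear-elastic solve
#'
#' Assembles the tet10 isoparametric stiffness (4-point Gauss rule, compiled
#' element loop), distributes the total load equally over the head-load
#' nodes, eliminates the fixed degrees of freedom, and solves the sparse
#' symmetric positive-definite system by a Cholesky factorisation.
#'
#' @param mesh A `tet_mesh` with assigned `E`, `nu`.
#' @param sets A `node_sets`.
#' @param load A [load_case()].
#' @return An `fe_result`: `displacement` (n x 3 mm), `mean_u_head` (mm),
#'   `stiffness` (N/mm), `reactions` at fixed dofs, diagnostics.
#' @export
solve_static <- function(mesh, sets, load) {
  if (any(is.na(mesh$E))) stop("element moduli not assigned")
  if (any(mesh$E <= 0)) stop("non-positive element modulus")
  fixed_nodes <- union(sets$fixed_endplate, sets$fixed_caudal)
  if (length(fixed_nodes) == 0) stop("no fixed nodes: rigid-body modes")
  nn <- nrow(mesh$nodes)
  ndof <- 3 * nn
  t0 <- proc.time()[3]

  K <- assemble_stiffness(mesh)
  f <- numeric(ndof)
  if (load$magnitude > 0) {
    per <- load$magnitude / length(sets$head_load)
    for (c_ in 1:3)
      f[3 * (sets$head_load - 1) + c_] <- per * load$direction[c_]
  }
  fixed_dofs <- as.vector(outer(1:3, 3 * (fixed_nodes - 1), `+`))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- K[free, free]
  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, f[free])),
    error = function(e) stop("linear solve failed (singular or ",
                             "under-constrained system): ",
                             conditionMessage(e)))
  u <- numeric(ndof)
  u[free] <- uf
  resid <- max(abs(Kff %*% uf - f[free])) / max(max(abs(f)), 1e-300)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  um <- sqrt(rowSums(U[sets$head_measure, , drop = FALSE]^2))
  mean_u <- mean(um)
  r_full <- as.numeric(K %*% u) - f
  structure(list(
    displacement = U,
    mean_u_head = mean_u,
    stiffness = if (mean_u > 0) load$magnitude / mean_u else NA_real_,
    reactions = r_full[fixed_dofs],
    fixed_dofs = fixed_dofs,
    load = load,
    n_elements = nrow(mesh$elements),
    n_nodes = nn,
    residual = resid,
    solve_seconds = proc.time()[3] - t0), class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf("fe_result: %d nodes, %d elements\n", x$n_nodes, x$n_elements))
  cat(sprintf("  mean head displacement %.5g mm, stiffness %.2f N/mm\n",
              x$mean_u_head, x$stiffness))
  invisible(x)
}

# sparse global stiffness (dsCMatrix), assembled in element chunks
assemble_stiffness <- function(mesh, chunk = 4000L) {
  ndof <- 3 * nrow(mesh$nodes)
  nel <- nrow(mesh$elements)
  K <- NULL
  for (s in seq(1L, nel, by = chunk)) {
    e <- s:min(s + chunk - 1L, nel)
    tr <- .tet10_assemble_cpp(mesh$nodes, mesh$elements[e, , drop = FALSE],
                              mesh$E[e], mesh$nu[e])
    Kb <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                               dims = c(ndof, ndof))
    K <- if (is.null(K)) Kb else K + Kb
  }
  Matrix::forceSymmetric(K, uplo = "L")
}

#' Pull-out stiffness from a solved result
#'
#' `k = load / mean_u_head` — the applied tensile load divided by the mean
#' displacement magnitude of the head measurement nodes.
#' @param result An `fe_result`.
#' @param load A [load_case()].
#' @return Stiffness, N/mm.
#' @export
compute_stiffness <- function(result, load) {
  if (!is.finite(result$mean_u_head) || result$mean_u_head <= 0)
    stop("zero head displacement under nonzero load: model over-constrained?")
  load$magnitude / result$mean_u_head
}

#' Mesh-convergence sweep
#'
#' Re-meshes the assembly at each element size, re-assigns materials, solves
#' the load case, and tabulates element count, mean head displacement and
#' stiffness. Convergence is declared at the first size whose mean head
#' displacement changes by less than `tol` (relative) from the previous
#' (coarser) refinement.
#'
#' @param assy An [assembly()] with the loaded screw placed.
#' @param sizes Element sizes to sweep, mm (default the nine sizes 2.0-6.0).
#' @param volume Calibrated [ct_volume()] for material assignment.
#' @param model [density_modulus_model()].
#' @param head_plan The loaded screw's [trajectory_plan()].
#' @param load A [load_case()].
#' @param tol Relative convergence tolerance on mean head displacement.
#' @param endplate_region,caudal_fraction Passed to [define_node_sets()].
#' @return A `convergence_table` data.frame (one row per size) with attribute
#'   `converged_at` (size, or NA).
#' @export
convergence_sweep <- function(assy, sizes = seq(2, 6, by = 0.5), volume,
                              model, head_plan, load, tol = 0.02,
                              endplate_region = list(depth = 3),
                              caudal_fraction = 1 / 3) {
  if (length(sizes) < 2) stop("at least two sizes are required")
  sizes <- sort(sizes, decreasing = TRUE)  # coarse to fine
  rows <- lapply(sizes, function(h) {
    res <- tryCatch({
      mesh <- tetrahedralize(assy, h)
      mesh <- assign_element_materials(mesh, volume, model)
      sets <- define_node_sets(mesh, endplate_region, caudal_fraction,
                               head_spec = list(plan = head_plan))
      r <- solve_static(mesh, sets, load)
      data.frame(size_mm = h, n_elements = r$n_elements,
                 n_nodes = r$n_nodes, mean_u_head_mm = r$mean_u_head,
                 stiffness_n_mm = r$stiffness,
                 solve_seconds = r$solve_seconds, error = NA_character_)
    }, error = function(e)
      data.frame(size_mm = h, n_elements = NA_integer_, n_nodes = NA_integer_,
                 mean_u_head_mm = NA_real_, stiffness_n_mm = NA_real_,
                 solve_seconds = NA_real_, error = conditionMessage(e)))
    res
  })
  tab <- do.call(rbind, rows)
  tab$rel_change <- c(NA, abs(diff(tab$mean_u_head_mm)) /
                        utils::head(tab$mean_u_head_mm, -1))
  conv <- which(!is.na(tab$rel_change) & tab$rel_change < tol)
  attr(tab, "converged_at") <- if (length(conv) > 0) tab$size_mm[conv[1]] else NA
  class(tab) <- c("convergence_table", "data.frame")
  tab
}
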