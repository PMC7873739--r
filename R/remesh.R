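#' Uniform isotropic remeshing
#'
#' Incremental remeshing toward a target edge length: per pass, edges longer
#' than 4/3 of the target are split at their midpoint, edges shorter than 4/5
#' of the target are collapsed (with manifold link-condition guards), and
#' vertices are relaxed tangentially and projected back onto the input
#' surface. Feature edges whose dihedral normal deviation exceeds
#' `sharp_angle_deg` are treated as constraints: crease vertices move only
#' along the crease, corner vertices (3+ creases) never move, and collapses
#' never cross a crease — so sharp geometry (e.g. cube edges) is preserved.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param target_edge Target edge length, mm.
#' @param sharp_angle_deg Dihedral angle threshold for feature edges,
#'   degrees.
#' @param passes Number of split/collapse/relax passes.
#' @return A watertight [surface_mesh()] whose median edge length is close to
#'   the target.
#' @export
remesh_uniform <- function(mesh, target_edge, sharp_angle_deg = 60,
                           passes = 5) {
  stopifnot(target_edge > 0)
  if (!is_watertight(mesh)) stop("remesh_uniform requires a watertight mesh")
  original <- mesh
  V <- mesh$vertices
  F <- mesh$faces
  for (p in seq_len(passes)) {
    sp <- remesh_split(V, F, 4 / 3 * target_edge)
    V <- sp$V; F <- sp$F
    cl <- remesh_collapse(V, F, 4 / 5 * target_edge, sharp_angle_deg)
    V <- cl$V; F <- cl$F
    rx <- remesh_relax(V, F, original, sharp_angle_deg)
    V <- rx
  }
  out <- surface_mesh(V, F)
  if (!is_watertight(out))
    stop("remeshing failed to preserve a watertight mesh")
  out
}

# classify edges/vertices by dihedral angle; returns edge table with faces,
# sharp flag and per-vertex crease class (0 smooth, 1 crease, 2 corner/fixed)
remesh_features <- function(V, F, sharp_angle_deg) {
  m <- nrow(F)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  face_of <- rep(seq_len(m), 3)
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- a * (nrow(V) + 1) + b
  o <- order(key)
  # watertight: each key appears exactly twice, adjacent after sorting
  k <- key[o]
  f1 <- face_of[o][c(TRUE, FALSE)]
  f2 <- face_of[o][c(FALSE, TRUE)]
  ea <- a[o][c(TRUE, FALSE)]
  eb <- b[o][c(TRUE, FALSE)]
  n <- mesh_face_normals(surface_mesh(V, F))
  cosang <- rowSums(n[f1, , drop = FALSE] * n[f2, , drop = FALSE])
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  sharp <- ang >= sharp_angle_deg
  ns <- tabulate(c(ea[sharp], eb[sharp]), nbins = nrow(V))
  vclass <- ifelse(ns >= 3, 2L, ifelse(ns >= 1, 1L, 0L))
  list(v1 = ea, v2 = eb, f1 = f1, f2 = f2, sharp = sharp, vclass = vclass)
}

remesh_split <- function(V, F, max_len) {
  repeat {
    m <- nrow(F)
    ft <- remesh_features(V, F, 361)  # features not needed, just edge table
    len <- sqrt(rowSums((V[ft$v1, , drop = FALSE] - V[ft$v2, , drop = FALSE])^2))
    to_split <- len > max_len
    if (!any(to_split)) return(list(V = V, F = F))
    nv0 <- nrow(V)
    mid_id <- integer(length(ft$v1))
    mid_id[to_split] <- nv0 + seq_len(sum(to_split))
    V <- rbind(V, (V[ft$v1[to_split], , drop = FALSE] +
                   V[ft$v2[to_split], , drop = FALSE]) / 2)
    # midpoint id per face corner-edge (e12, e23, e31)
    key_of <- function(x, y) pmin(x, y) * (nv0 + 1) + pmax(x, y)
    ekey <- key_of(ft$v1, ft$v2)
    lookup <- function(x, y) {
      id <- mid_id[match(key_of(x, y), ekey)]
      id[is.na(id)] <- 0L
      id
    }
    m12 <- lookup(F[, 1], F[, 2])
    m23 <- lookup(F[, 2], F[, 3])
    m31 <- lookup(F[, 3], F[, 1])
    case <- (m12 > 0) + 2L * (m23 > 0) + 4L * (m31 > 0)
    newF <- vector("list", 8)
    v1 <- F[, 1]; v2 <- F[, 2]; v3 <- F[, 3]
    sel <- function(cs) case == cs
    add <- function(cs, ...) {
      s <- sel(cs)
      if (!any(s)) return(NULL)
      tri <- list(...)
      do.call(rbind, lapply(tri, function(tt)
        cbind(tt[[1]][s], tt[[2]][s], tt[[3]][s])))
    }
    L <- list(v1 = v1, v2 = v2, v3 = v3, m12 = m12, m23 = m23, m31 = m31)
    tri <- function(a, b, c_) list(L[[a]], L[[b]], L[[c_]])
    parts <- list(
      add(0L, tri("v1", "v2", "v3")),
      add(1L, tri("v1", "m12", "v3"), tri("m12", "v2", "v3")),
      add(2L, tri("v2", "m23", "v1"), tri("m23", "v3", "v1")),
      add(4L, tri("v3", "m31", "v2"), tri("m31", "v1", "v2")),
      add(3L, tri("m12", "v2", "m23"), tri("v1", "m12", "m23"),
               tri("v1", "m23", "v3")),
      add(6L, tri("m23", "v3", "m31"), tri("v2", "m23", "m31"),
               tri("v2", "m31", "v1")),
      add(5L, tri("v1", "m12", "m31"), tri("m12", "v2", "v3"),
               tri("m12", "v3", "m31")),
      add(7L, tri("v1", "m12", "m31"), tri("m12", "v2", "m23"),
               tri("m31", "m23", "v3"), tri("m12", "m23", "m31"))
    )
    F <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    storage.mode(F) <- "integer"
  }
}

remesh_collapse <- function(V, F, min_len, sharp_angle_deg, rounds = 25) {
  for (r in seq_len(rounds)) {
    res <- remesh_collapse_round(V, F, min_len, sharp_angle_deg)
    if (res$n_collapsed == 0) break
    V <- res$V; F <- res$F
  }
  list(V = V, F = F)
}

remesh_collapse_round <- function(V, F, min_len, sharp_angle_deg) {
  if (nrow(F) <= 8) return(list(V = V, F = F, n_collapsed = 0L))
  ft <- remesh_features(V, F, sharp_angle_deg)
  len <- sqrt(rowSums((V[ft$v1, , drop = FALSE] - V[ft$v2, , drop = FALSE])^2))
  cand <- which(len < min_len)
  if (length(cand) == 0) return(list(V = V, F = F, n_collapsed = 0L))
  cand <- cand[order(len[cand])]
  # adjacency list
  e2 <- rbind(cbind(ft$v1, ft$v2), cbind(ft$v2, ft$v1))
  adj <- split(e2[, 2], e2[, 1])
  adj_of <- function(v) adj[[as.character(v)]] %||% integer(0)
  touched <- logical(nrow(V))
  vmap <- seq_len(nrow(V))
  vcl <- ft$vclass
  ncol_ <- 0L
  for (ei in cand) {
    a <- ft$v1[ei]; b <- ft$v2[ei]
    if (touched[a] || touched[b]) next
    ca <- vcl[a]; cb <- vcl[b]
    if (ca == 2L && cb == 2L) next              # two corners: never merge
    if (ca >= 1L && cb >= 1L && !ft$sharp[ei]) next  # would cross a crease
    na <- adj_of(a); nb <- adj_of(b)
    common <- intersect(na, nb)
    if (length(common) != 2) next               # link condition
    # target position: keep the more constrained vertex's position
    pos <- if (ca > cb) V[a, ] else if (cb > ca) V[b, ] else (V[a, ] + V[b, ]) / 2
    V[a, ] <- pos
    vmap[b] <- a
    vcl[a] <- max(ca, cb)
    touched[c(a, b, na, nb)] <- TRUE
    ncol_ <- ncol_ + 1L
  }
  F2 <- matrix(vmap[F], ncol = 3)
  keep <- F2[, 1] != F2[, 2] & F2[, 2] != F2[, 3] & F2[, 1] != F2[, 3]
  F2 <- F2[keep, , drop = FALSE]
  # drop unreferenced vertices
  used <- sort(unique(as.vector(F2)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  list(V = V[used, , drop = FALSE],
       F = matrix(remap[F2], ncol = 3), n_collapsed = ncol_)
}

remesh_relax <- function(V, F, original, sharp_angle_deg, lambda = 0.5) {
  ft <- remesh_features(V, F, sharp_angle_deg)
  e2 <- rbind(cbind(ft$v1, ft$v2), cbind(ft$v2, ft$v1))
  nb <- rowsum(V[e2[, 2], , drop = FALSE], e2[, 1], reorder = TRUE)
  ids <- as.integer(rownames(nb))
  deg <- tabulate(e2[, 1], nbins = nrow(V))[ids]
  centroid <- nb / deg
  vn <- mesh_vertex_normals(surface_mesh(V, F))
  Vn <- V
  smooth_ids <- ids[ft$vclass[ids] == 0L]
  if (length(smooth_ids) > 0) {
    d <- centroid[match(smooth_ids, ids), , drop = FALSE] -
      V[smooth_ids, , drop = FALSE]
    nrm <- vn[smooth_ids, , drop = FALSE]
    d_t <- d - nrm * rowSums(d * nrm)   # tangential component only
    moved <- V[smooth_ids, , drop = FALSE] + lambda * d_t
    proj <- closest_point_on_mesh(moved, original)
    Vn[smooth_ids, ] <- proj$point
  }
  # crease vertices: average along their sharp neighbours only (stays on
  # straight creases exactly); corners stay put
  crease <- which(ft$vclass == 1L)
  if (length(crease) > 0) {
    se <- cbind(c(ft$v1[ft$sharp], ft$v2[ft$sharp]),
                c(ft$v2[ft$sharp], ft$v1[ft$sharp]))
    se <- se[se[, 1] %in% crease, , drop = FALSE]
    if (nrow(se) > 0) {
      snb <- rowsum(V[se[, 2], , drop = FALSE], se[, 1], reorder = TRUE)
      sids <- as.integer(rownames(snb))
      sdeg <- tabulate(se[, 1], nbins = nrow(V))[sids]
      two <- sdeg == 2
      mid <- snb[two, , drop = FALSE] / 2
      tgt <- sids[two]
      Vn[tgt, ] <- V[tgt, , drop = FALSE] +
        lambda * (mid - V[tgt, , drop = FALSE])
    }
  }
  Vn
}
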