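#' Write a mesh to STL
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param binary Write binary STL (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices; F <- mesh$faces
  n <- mesh_face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (f in seq_len(nrow(F))) {
      writeBin(as.numeric(c(n[f, ], t(V[F[f, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (f in seq_len(nrow(F))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[f, 1], n[f, 2], n[f, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        v <- V[F[f, k], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Read a mesh from STL (binary or ASCII)
#'
#' Duplicate vertices shared between facets are welded.
#' @param path STL file path.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (!is_ascii) {
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    tris <- matrix(0, nf * 3, 3)
    for (f in seq_len(nf)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      tris[(3 * f - 2):(3 * f), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
    close(con)
  } else {
    close(con)
    lines <- readLines(path)
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    parts <- strsplit(trimws(vx), "\\s+")
    tris <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  }
  nf <- nrow(tris) / 3
  mesh <- surface_mesh(tris, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
  weld_vertices(mesh)
}
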