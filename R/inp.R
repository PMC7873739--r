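#' Export a model to an Abaqus INP deck
#'
#' Writes `*NODE`, `*ELEMENT, TYPE=C3D10`, per-material `*ELSET` bins
#' (element modulus rounded to 6 significant digits for binning, export
#' only — the in-memory mesh keeps per-element values), `*MATERIAL` /
#' `*ELASTIC`, `*BOUNDARY` for the fixed sets, and `*CLOAD` equal nodal
#' forces on the head-load set, so the model can be cross-validated in an
#' external solver.
#'
#' @param mesh A `tet_mesh` with assigned materials.
#' @param sets A `node_sets`.
#' @param load A [load_case()].
#' @param path Output file.
#' @export
export_inp <- function(mesh, sets, load, path) {
  if (any(is.na(mesh$E))) stop("element moduli not assigned")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("*HEADING")
  w("Pull-out model export (tet10, heterogeneous linear elastic)")
  w("*NODE")
  n <- mesh$nodes
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(n)),
                     n[, 1], n[, 2], n[, 3]), con)
  w("*ELEMENT, TYPE=C3D10")
  el <- mesh$elements
  writeLines(paste0(seq_len(nrow(el)), ", ",
                    apply(el, 1, paste, collapse = ", ")), con)
  ebin <- signif(mesh$E, 6)
  nubin <- mesh$nu
  key <- paste0(ebin, "_", nubin)
  for (k in unique(key)) {
    ids <- which(key == k)
    nm <- paste0("MAT_", match(k, unique(key)))
    w("*ELSET, ELSET=%s", nm)
    writeLines(paste(format_chunks(ids), collapse = "\n"), con)
    w("*SOLID SECTION, ELSET=%s, MATERIAL=%s", nm, nm)
    w("*MATERIAL, NAME=%s", nm)
    w("*ELASTIC")
    w("%.9g, %.9g", ebin[ids[1]], nubin[ids[1]])
  }
  for (snm in c("fixed_endplate", "fixed_caudal")) {
    w("*NSET, NSET=%s", toupper(snm))
    writeLines(paste(format_chunks(sets[[snm]]), collapse = "\n"), con)
  }
  w("*NSET, NSET=HEAD_LOAD")
  writeLines(paste(format_chunks(sets$head_load), collapse = "\n"), con)
  w("*STEP")
  w("*STATIC")
  w("*BOUNDARY")
  w("FIXED_ENDPLATE, 1, 3, 0.")
  w("FIXED_CAUDAL, 1, 3, 0.")
  w("*CLOAD")
  per <- load$magnitude / length(sets$head_load)
  for (c_ in 1:3)
    if (abs(load$direction[c_]) > 0)
      w("HEAD_LOAD, %d, %.9g", c_, per * load$direction[c_])
  w("*END STEP")
  invisible(path)
}

format_chunks <- function(ids, per_line = 12) {
  grp <- split(ids, ceiling(seq_along(ids) / per_line))
  vapply(grp, function(g) paste(g, collapse = ", "), character(1))
}

#' Read back nodes and elements from an INP deck
#'
#' Minimal reader for round-trip checks of decks written by [export_inp()].
#' @param path INP file.
#' @return List with `nodes`, `elements`, and `elsets` (element id vectors
#'   per material bin).
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  kw <- grep("^\\*", lines)
  get_block <- function(i) {
    j <- kw[kw > i]
    end <- if (length(j) > 0) min(j) - 1 else length(lines)
    if (end < i + 1) return(character(0))
    lines[(i + 1):end]
  }
  nodes <- elements <- NULL
  elsets <- list()
  for (i in kw) {
    key <- toupper(lines[i])
    if (startsWith(key, "*NODE")) {
      vals <- do.call(rbind, lapply(strsplit(get_block(i), ","), as.numeric))
      nodes <- vals[order(vals[, 1]), 2:4, drop = FALSE]
    } else if (startsWith(key, "*ELEMENT")) {
      vals <- do.call(rbind, lapply(strsplit(get_block(i), ","), as.numeric))
      elements <- matrix(as.integer(vals[order(vals[, 1]), 2:11]), ncol = 10)
    } else if (startsWith(key, "*ELSET")) {
      nm <- sub(".*ELSET=([^,]+).*", "\\1", key)
      ids <- as.integer(unlist(strsplit(paste(get_block(i), collapse = ","),
                                        ",")))
      elsets[[nm]] <- ids[!is.na(ids)]
    }
  }
  list(nodes = nodes, elements = elements, elsets = elsets)
}
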