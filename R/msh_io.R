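# Gmsh MSH ASCII v2.2 interchange and legacy-VTK visualization export.

# Default integer physical tags for the tissue labels.
default_tag_map <- function() {
  stats::setNames(seq_along(tissue_labels()), tissue_labels())
}

#' Write a head mesh as Gmsh MSH ASCII v2.2
#'
#' One physical tag per tissue label (tetrahedral elements, type 4).
#' Coordinates are written in meters.
#'
#' @param mesh A [head_mesh()].
#' @param path Output file path.
#' @param tag_map Named integer vector mapping tissue label to physical tag;
#'   defaults to the package's fixed assignment.
#' @return Invisibly, `path`.
#' @export
write_msh <- function(mesh, path, tag_map = default_tag_map()) {
  stopifnot(inherits(mesh, "head_mesh"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes"), con)
  nn <- nrow(mesh$nodes)
  writeLines(as.character(nn), con)
  writeLines(
    sprintf(
      "%d %.17g %.17g %.17g",
      seq_len(nn), mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]
    ),
    con
  )
  writeLines(c("$EndNodes", "$Elements"), con)
  m <- nrow(mesh$elements)
  writeLines(as.character(m), con)
  tags <- tag_map[mesh$tissue]
  if (any(is.na(tags))) {
    stop(
      "tag_map is missing tissue(s): ",
      paste(setdiff(unique(mesh$tissue), names(tag_map)), collapse = ", ")
    )
  }
  writeLines(
    sprintf(
      "%d 4 2 %d %d %d %d %d %d",
      seq_len(m), tags, tags,
      mesh$elements[, 1L], mesh$elements[, 2L],
      mesh$elements[, 3L], mesh$elements[, 4L]
    ),
    con
  )
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH ASCII v2.2 tetrahedral mesh
#'
#' Parses the v2.2 ASCII dialect with tetrahedral volume elements (type 4)
#' whose first (physical) tag identifies the tissue via `tag_map`.
#' Non-tetrahedral volume elements, unknown tags and other MSH versions are
#' rejected with the offending line number. Elements with negative signed
#' volume are repaired by a node swap at read time.
#'
#' @param path MSH file path.
#' @param tag_map Named integer vector, tissue label -> physical tag.
#' @param units `"m"` (default) or `"mm"`: units of the stored coordinates;
#'   millimeters are converted to the internal SI meters.
#' @param conductivities Named vector, tissue -> S/m, filled per element.
#' @return A [head_mesh()].
#' @export
read_msh <- function(path, tag_map = default_tag_map(), units = c("m", "mm"),
                     conductivities = conductivity_defaults()) {
  units <- match.arg(units)
  lines <- readLines(path)
  fail <- function(lineno, msg) {
    stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
  }
  sec <- function(name) {
    i <- match(paste0("$", name), lines)
    if (is.na(i)) fail(1L, paste0("missing $", name, " section"))
    i
  }
  i_fmt <- sec("MeshFormat")
  fmt <- strsplit(trimws(lines[i_fmt + 1L]), "\\s+")[[1L]]
  if (fmt[1L] != "2.2") {
    fail(i_fmt + 1L, paste0(
      "unsupported MSH version '", fmt[1L], "' (only ASCII v2.2 is read)"
    ))
  }
  if (fmt[2L] != "0") fail(i_fmt + 1L, "binary MSH files are not supported")

  i_nodes <- sec("Nodes")
  nn <- suppressWarnings(as.integer(lines[i_nodes + 1L]))
  if (is.na(nn)) fail(i_nodes + 1L, "invalid node count")
  node_rows <- lines[i_nodes + 1L + seq_len(nn)]
  nm <- matrix(
    as.numeric(unlist(strsplit(trimws(node_rows), "\\s+"))),
    ncol = 4L, byrow = TRUE
  )
  if (anyNA(nm)) fail(i_nodes + 2L, "malformed node line")
  nodes <- matrix(0, nn, 3L)
  nodes[nm[, 1L], ] <- nm[, 2:4]
  if (units == "mm") nodes <- nodes / 1e3

  i_el <- sec("Elements")
  m <- suppressWarnings(as.integer(lines[i_el + 1L]))
  if (is.na(m)) fail(i_el + 1L, "invalid element count")
  rev_map <- stats::setNames(names(tag_map), tag_map)
  el <- matrix(0L, m, 4L)
  tissue <- character(m)
  kept <- 0L
  for (k in seq_len(m)) {
    lineno <- i_el + 1L + k
    tok <- suppressWarnings(as.integer(strsplit(trimws(lines[lineno]), "\\s+")[[1L]]))
    if (anyNA(tok) || length(tok) < 3L) fail(lineno, "malformed element line")
    etype <- tok[2L]
    ntags <- tok[3L]
    if (etype != 4L) {
      fail(lineno, sprintf(
        "unsupported element type %d (only 4-node tetrahedra are read)", etype
      ))
    }
    if (length(tok) != 3L + ntags + 4L) fail(lineno, "wrong element field count")
    ptag <- tok[4L]
    lab <- rev_map[as.character(ptag)]
    if (is.na(lab)) fail(lineno, sprintf("unknown physical tag %d", ptag))
    kept <- kept + 1L
    el[kept, ] <- tok[3L + ntags + 1:4]
    tissue[kept] <- lab
  }
  head_mesh(
    nodes, el[seq_len(kept), , drop = FALSE], tissue[seq_len(kept)],
    conductivity = unname(conductivities[tissue[seq_len(kept)]])
  )
}

#' Write a legacy-VTK unstructured-grid file for visualization
#'
#' Cell data: integer tissue tag and, when a field solution is supplied, the
#' element field magnitude `|E|` in V/m.
#'
#' @param mesh A [head_mesh()].
#' @param path Output `.vtk` path.
#' @param field Optional [compute_efield()] result.
#' @param tag_map Tissue tag assignment.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(mesh, path, field = NULL, tag_map = default_tag_map()) {
  stopifnot(inherits(mesh, "head_mesh"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  nn <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "tesfield volume conductor", "ASCII", "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", nn)
  ), con)
  writeLines(
    sprintf("%.9g %.9g %.9g", mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
    con
  )
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(
    sprintf(
      "4 %d %d %d %d",
      mesh$elements[, 1L] - 1L, mesh$elements[, 2L] - 1L,
      mesh$elements[, 3L] - 1L, mesh$elements[, 4L] - 1L
    ),
    con
  )
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(tag_map[mesh$tissue]), con)
  if (!is.null(field)) {
    writeLines(c("SCALARS E_magnitude double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", field$magnitude), con)
  }
  invisible(path)
}
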