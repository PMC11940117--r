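#' Tissue labels recognised by the volume-conductor model
#'
#' The five head compartments plus the optional ventricle core and the two
#' electrode-assembly materials (saline gel, rubber pad) used by the extruded
#' electrode model.
#'
#' @return Character vector of tissue labels.
#' @export
tissue_labels <- function() {
  c("SCALP", "SKULL", "CSF", "GM", "WM", "VENTRICLE", "GEL", "PAD")
}

#' Default tissue conductivities (S/m)
#'
#' Fixed isotropic conductivities for the head compartments: scalp 0.465,
#' skull 0.01, CSF 1.654, grey matter 0.275, white matter 0.126 S/m, with the
#' electrode pad at 29.4 S/m and the saline gel interface at 1 S/m. Ventricles
#' are treated as CSF-filled (same conductivity).
#'
#' @return Named numeric vector mapping tissue label to conductivity in S/m.
#' @export
#' @examples
#' conductivity_defaults()[["SKULL"]]
conductivity_defaults <- function() {
  c(
    SCALP = 0.465, SKULL = 0.01, CSF = 1.654, GM = 0.275, WM = 0.126,
    VENTRICLE = 1.654, GEL = 1.0, PAD = 29.4
  )
}

#' Construct a labelled tetrahedral head mesh
#'
#' The volume-conductor data model used throughout the package: node
#' coordinates in meters, tetrahedral connectivity, one tissue label and one
#' conductivity per element. Conductivity may be a positive scalar per element
#' or a symmetric positive-definite tensor stored as a 6-column matrix
#' (xx, yy, zz, xy, xz, yz).
#'
#' @param nodes Numeric matrix, n x 3, node coordinates in meters.
#' @param elements Integer matrix, m x 4, 1-based node indices per tetrahedron.
#' @param tissue Character vector of length m with labels from
#'   [tissue_labels()].
#' @param conductivity Numeric vector of length m (scalar, S/m) or an m x 6
#'   matrix of tensor components. Defaults to [conductivity_defaults()] looked
#'   up by tissue.
#' @param fix_orientation If `TRUE` (default), elements with negative signed
#'   volume are repaired by swapping two nodes so that all volumes are
#'   positive under the package's ordering convention.
#' @return An object of class `head_mesh`: a list with `nodes`, `elements`,
#'   `tissue`, `conductivity`, and cached per-element `volume` (m^3).
#' @export
head_mesh <- function(nodes, elements, tissue, conductivity = NULL,
                      fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(nodes) <- NULL
  dimnames(elements) <- NULL
  if (ncol(nodes) != 3L) stop("`nodes` must have 3 columns (x, y, z in meters)")
  if (ncol(elements) != 4L) stop("`elements` must have 4 columns (tetrahedra)")
  if (nrow(elements) == 0L || nrow(nodes) == 0L) stop("empty mesh")
  if (length(tissue) != nrow(elements)) {
    stop("`tissue` length must equal the number of elements")
  }
  tissue <- as.character(tissue)
  unknown <- setdiff(unique(tissue), tissue_labels())
  if (length(unknown) > 0L) {
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  }
  if (max(elements) > nrow(nodes) || min(elements) < 1L) {
    stop("element refers to a node index outside 1..nrow(nodes)")
  }
  if (is.null(conductivity)) {
    conductivity <- unname(conductivity_defaults()[tissue])
  }
  if (is.matrix(conductivity)) {
    if (nrow(conductivity) != nrow(elements) || ncol(conductivity) != 6L) {
      stop("tensor conductivity must be an m x 6 matrix (xx,yy,zz,xy,xz,yz)")
    }
  } else if (length(conductivity) != nrow(elements)) {
    stop("`conductivity` length must equal the number of elements")
  }

  vol <- tet_signed_volume(nodes, elements)
  if (fix_orientation && any(vol < 0)) {
    neg <- vol < 0
    tmp <- elements[neg, 3L]
    elements[neg, 3L] <- elements[neg, 4L]
    elements[neg, 4L] <- tmp
    vol <- abs(vol)
  }

  structure(
    list(
      nodes = nodes, elements = elements, tissue = tissue,
      conductivity = conductivity, volume = vol
    ),
    class = "head_mesh"
  )
}

#' @export
print.head_mesh <- function(x, ...) {
  cat("<head_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elements), " tets\n",
    sep = ""
  )
  tab <- tapply(x$volume, x$tissue, sum) * 1e6
  for (t in names(tab)) {
    cat(sprintf("  %-9s %8.2f cm^3\n", t, tab[[t]]))
  }
  invisible(x)
}

# Signed volume of each tetrahedron (m^3); positive under the package's
# node-ordering convention.
tet_signed_volume <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  b <- nodes[elements[, 2L], , drop = FALSE]
  c_ <- nodes[elements[, 3L], , drop = FALSE]
  d <- nodes[elements[, 4L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  w <- d - a
  det <- u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
    u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
    u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])
  det / 6
}

# Element centroids, m x 3.
tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1L], , drop = FALSE] +
    mesh$nodes[mesh$elements[, 2L], , drop = FALSE] +
    mesh$nodes[mesh$elements[, 3L], , drop = FALSE] +
    mesh$nodes[mesh$elements[, 4L], , drop = FALSE]) / 4
}

# Normalized radius-ratio quality 3 * r_in / r_circ per element, 1 for the
# regular tetrahedron, -> 0 for degenerate elements.
tet_quality <- function(nodes, elements) {
  a <- nodes[elements[, 1L], , drop = FALSE]
  b <- nodes[elements[, 2L], , drop = FALSE]
  c_ <- nodes[elements[, 3L], , drop = FALSE]
  d <- nodes[elements[, 4L], , drop = FALSE]
  vol <- abs(tet_signed_volume(nodes, elements))

  tri_area <- function(p, q, r) {
    u <- q - p
    v <- r - p
    cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
    cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
    cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  s <- tri_area(b, c_, d) + tri_area(a, c_, d) +
    tri_area(a, b, d) + tri_area(a, b, c_)
  r_in <- 3 * vol / s

  # circumradius via the Cayley-Menger-free formula with edge products
  elen2 <- function(p, q) rowSums((p - q)^2)
  # opposite edge products: (AB*CD), (AC*BD), (AD*BC)
  p1 <- sqrt(elen2(a, b) * elen2(c_, d))
  p2 <- sqrt(elen2(a, c_) * elen2(b, d))
  p3 <- sqrt(elen2(a, d) * elen2(b, c_))
  # Crelle: 24 V R = sqrt((p1+p2+p3)(-p1+p2+p3)(p1-p2+p3)(p1+p2-p3)) / ... :
  # R = sqrt((p1+p2+p3)(-p1+p2+p3)(p1-p2+p3)(p1+p2-p3)) / (24 V)
  arg <- pmax((p1 + p2 + p3) * (-p1 + p2 + p3) * (p1 - p2 + p3) * (p1 + p2 - p3), 0)
  r_circ <- sqrt(arg) / (24 * vol)
  q <- 3 * r_in / r_circ
  q[!is.finite(q)] <- 0
  q
}

#' Validate a head mesh
#'
#' Checks the structural invariants of a [head_mesh()]: all referenced node
#' indices exist, elements have four distinct nodes, signed volumes are
#' positive, conductivities are positive (scalars) or SPD (tensors), and
#' reports per-tissue volumes and the minimum element quality.
#'
#' @param mesh A `head_mesh`.
#' @return A list of class `mesh_validation` with `tissue_volumes` (a tibble:
#'   tissue, n_elements, volume_cm3), `min_quality`, `n_orphan_nodes`, and a
#'   character vector `violations` (empty when the mesh is valid).
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "head_mesh"))
  violations <- character()

  el <- mesh$elements
  if (any(el < 1L) || any(el > nrow(mesh$nodes))) {
    violations <- c(violations, "element references a missing node")
  }
  dup <- el[, 1L] == el[, 2L] | el[, 1L] == el[, 3L] | el[, 1L] == el[, 4L] |
    el[, 2L] == el[, 3L] | el[, 2L] == el[, 4L] | el[, 3L] == el[, 4L]
  if (any(dup)) {
    violations <- c(violations, sprintf(
      "%d element(s) with repeated nodes", sum(dup)
    ))
  }
  vol <- tet_signed_volume(mesh$nodes, mesh$elements)
  if (any(vol <= 0)) {
    violations <- c(violations, sprintf(
      "%d inverted element(s) (non-positive signed volume)", sum(vol <= 0)
    ))
  }
  if (is.matrix(mesh$conductivity)) {
    spd <- tensor_is_spd(mesh$conductivity)
    if (!all(spd)) {
      violations <- c(violations, sprintf(
        "%d non-SPD conductivity tensor(s)", sum(!spd)
      ))
    }
  } else if (any(mesh$conductivity <= 0)) {
    violations <- c(violations, "non-positive scalar conductivity")
  }
  if (any(is.na(mesh$tissue))) {
    violations <- c(violations, "missing tissue label")
  }
  orphan <- setdiff(seq_len(nrow(mesh$nodes)), unique(as.vector(el)))
  if (length(orphan) > 0L) {
    violations <- c(violations, sprintf("%d orphan node(s)", length(orphan)))
  }

  vols <- tapply(abs(vol), mesh$tissue, sum)
  counts <- tapply(rep(1L, length(vol)), mesh$tissue, sum)
  tissue_volumes <- tibble::tibble(
    tissue = names(vols),
    n_elements = as.integer(counts[names(vols)]),
    volume_cm3 = as.numeric(vols) * 1e6
  )

  structure(
    list(
      tissue_volumes = tissue_volumes,
      total_volume_cm3 = sum(tissue_volumes$volume_cm3),
      min_quality = min(tet_quality(mesh$nodes, mesh$elements)),
      n_orphan_nodes = length(orphan),
      violations = violations
    ),
    class = "mesh_validation"
  )
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("<mesh_validation>\n")
  print(x$tissue_volumes)
  cat(sprintf("min element quality: %.3f\n", x$min_quality))
  if (length(x$violations) == 0L) {
    cat("no violations\n")
  } else {
    cat("violations:\n")
    for (v in x$violations) cat("  -", v, "\n")
  }
  invisible(x)
}

# TRUE per row for SPD 3x3 tensors given as (xx,yy,zz,xy,xz,yz): leading
# principal minors all positive (Sylvester).
tensor_is_spd <- function(tens) {
  xx <- tens[, 1L]; yy <- tens[, 2L]; zz <- tens[, 3L]
  xy <- tens[, 4L]; xz <- tens[, 5L]; yz <- tens[, 6L]
  m1 <- xx
  m2 <- xx * yy - xy^2
  m3 <- xx * (yy * zz - yz^2) - xy * (xy * zz - yz * xz) +
    xz * (xy * yz - yy * xz)
  m1 > 0 & m2 > 0 & m3 > 0
}

# Boundary facets of the mesh: triangles belonging to exactly one tet.
# Returns a list with `tri` (k x 3 node indices) and `element` (owning tet id).
boundary_facets <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  # the 4 faces opposite each local node, oriented outward for positive tets
  faces <- rbind(
    el[, c(2L, 3L, 4L)],
    el[, c(1L, 4L, 3L)],
    el[, c(1L, 2L, 4L)],
    el[, c(1L, 3L, 2L)]
  )
  owner <- rep(seq_len(m), times = 4L)
  key <- face_key(faces, nrow(mesh$nodes))
  keep <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  list(tri = faces[keep, , drop = FALSE], element = owner[keep])
}

# Unique sorted-face key as a double (node count < 2^17 keeps it exact).
face_key <- function(faces, nn) {
  s <- sort3_rows(faces)
  (s[, 1L] * as.double(nn) + s[, 2L]) * nn + s[, 3L]
}

# Row-wise ascending sort of a 3-column integer matrix.
sort3_rows <- function(m) {
  a <- m[, 1L]; b <- m[, 2L]; c_ <- m[, 3L]
  lo <- pmin(a, b); hi <- pmax(a, b)
  mid <- pmin(hi, c_); hi <- pmax(hi, c_)
  lo2 <- pmin(lo, mid); mid <- pmax(lo, mid)
  cbind(lo2, mid, hi, deparse.level = 0L)
}

# Areas and outward unit normals of triangles (k x 3 node index matrix).
# Normals oriented as given by the vertex order.
triangle_geometry <- function(nodes, tri) {
  a <- nodes[tri[, 1L], , drop = FALSE]
  b <- nodes[tri[, 2L], , drop = FALSE]
  c_ <- nodes[tri[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  nx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  ny <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  nz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  list(
    area = nrm / 2,
    normal = cbind(nx / nrm, ny / nrm, nz / nrm),
    centroid = (a + b + c_) / 3
  )
}
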