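# Geodesic sphere surface and layered-sphere tetrahedral mesh construction.

# Subdivided icosahedron on the unit sphere. Returns list(vertices = n x 3,
# faces = f x 3). subdiv = 0 gives the icosahedron (12 vertices, 20 faces);
# each level quadruples the face count.
icosphere <- function(subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    # midpoint of each edge, deduplicated by edge key
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uniq <- !duplicated(ekey)
    eu <- e[uniq, , drop = FALSE]
    mid <- (v[eu[, 1], , drop = FALSE] + v[eu[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    mid_id <- nrow(v) + match(ekey, ekey[uniq])
    v <- rbind(v, mid)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  list(vertices = v, faces = f)
}

# Split a stack of triangular prisms into tets with the monotone-staircase
# rule: per surface face, order the three column indices ascending (x < y < z);
# the prism between levels l (node offset o1) and l+1 (offset o2) splits into
# (x1,y1,z1,z2), (x1,y1,z2,y2), (x1,y2,z2,x2). Quad diagonals then depend only
# on the column pair, so adjacent prisms conform.
prism_stack_tets <- function(faces_sorted, o1, o2) {
  x1 <- faces_sorted[, 1L] + o1
  y1 <- faces_sorted[, 2L] + o1
  z1 <- faces_sorted[, 3L] + o1
  x2 <- faces_sorted[, 1L] + o2
  y2 <- faces_sorted[, 2L] + o2
  z2 <- faces_sorted[, 3L] + o2
  rbind(
    cbind(x1, y1, z1, z2),
    cbind(x1, y1, z2, y2),
    cbind(x1, y2, z2, x2)
  )
}

# Radial node shells for a layered sphere. Returns vector of radii from the
# outermost surface inward to (but excluding) 0, together with the tissue
# label of each inter-shell gap. wm_coarsen relaxes the radial step inside
# the innermost (WM) compartment where field gradients are mild.
radial_levels <- function(radii, labels, h, wm_coarsen = 2) {
  stopifnot(length(radii) == length(labels), all(diff(radii) < 0))
  levels <- radii[1L]
  gap_label <- character()
  for (k in seq_along(radii)) {
    r_out <- radii[k]
    r_in <- if (k < length(radii)) radii[k + 1L] else 0
    th <- r_out - r_in
    step <- if (k == length(radii)) h * wm_coarsen else h
    n_sub <- max(1L, ceiling(th / step))
    if (k == length(radii)) {
      # innermost compartment: stop one step short of the center; the last
      # gap is closed by a tet fan to the center point
      rr <- seq(r_out, r_in, length.out = n_sub + 1L)[-1L]
      rr <- rr[rr > 1e-12]
      if (length(rr) == 0L) rr <- r_out / 2
    } else {
      rr <- seq(r_out, r_in, length.out = n_sub + 1L)[-1L]
    }
    levels <- c(levels, rr)
    gap_label <- c(gap_label, rep(labels[k], length(rr)))
  }
  list(radii = levels, gap_label = gap_label)
}

#' Build a layered-sphere head mesh
#'
#' Constructs a conforming tetrahedral mesh of concentric spherical tissue
#' shells by radially stacking a geodesic (subdivided icosahedron) surface:
#' each radial gap becomes a layer of triangular prisms split into three
#' tetrahedra each, and the innermost gap is closed by a tetrahedral fan to
#' the center. No element crosses a tissue interface; interfaces are exact
#' node shells.
#'
#' @param spec A [phantom_spec()] giving outer radii per layer (meters).
#' @param subdiv Icosphere subdivision level (angular resolution);
#'   level s has `20 * 4^s` surface faces.
#' @param h Target radial edge length in meters. Must not exceed the thinnest
#'   layer.
#' @param wm_coarsen Radial coarsening factor applied inside the innermost
#'   (white matter) compartment, where the field varies slowly.
#' @param conductivities Named vector mapping tissue label to S/m; defaults to
#'   [conductivity_defaults()].
#' @return A [head_mesh()].
#' @export
build_layered_sphere <- function(spec, subdiv = 3L, h = 2e-3, wm_coarsen = 2,
                                 conductivities = conductivity_defaults()) {
  stopifnot(inherits(spec, "phantom_spec"))
  radii <- spec$radii
  labels <- spec$labels
  thick <- -diff(c(radii, 0))
  if (any(thick[-length(thick)] <= 0)) stop("degenerate (zero-thickness) layer")
  # each layer is radially subdivided into ceiling(thickness / h) sublayers,
  # so at least one element always spans each layer radially; layers thinner
  # than h simply get a single finer sublayer

  surf <- icosphere(subdiv)
  nv <- nrow(surf$vertices)
  lev <- radial_levels(radii, labels, h, wm_coarsen)
  nl <- length(lev$radii)

  # nodes: level-major blocks of the surface vertices, plus the center point
  nodes <- matrix(0, nrow = nv * nl + 1L, ncol = 3L)
  for (l in seq_len(nl)) {
    nodes[(l - 1L) * nv + seq_len(nv), ] <- surf$vertices * lev$radii[l]
  }
  center_id <- nv * nl + 1L

  faces_sorted <- sort3_rows(surf$faces)
  nf <- nrow(faces_sorted)

  n_gap <- nl - 1L
  tets <- vector("list", n_gap + 1L)
  tissue <- vector("list", n_gap + 1L)
  for (g in seq_len(n_gap)) {
    o1 <- (g - 1L) * nv
    o2 <- g * nv
    tets[[g]] <- prism_stack_tets(faces_sorted, o1, o2)
    tissue[[g]] <- rep(lev$gap_label[g], 3L * nf)
  }
  # central fan from the innermost shell
  o_in <- (nl - 1L) * nv
  tets[[n_gap + 1L]] <- cbind(
    faces_sorted[, 1L] + o_in, faces_sorted[, 2L] + o_in,
    faces_sorted[, 3L] + o_in, center_id
  )
  tissue[[n_gap + 1L]] <- rep(labels[length(labels)], nf)

  elements <- do.call(rbind, tets)
  tissue <- unlist(tissue)
  head_mesh(
    nodes, elements, tissue,
    conductivity = unname(conductivities[tissue])
  )
}
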