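# Electrode placement on the spherical scalp: 10-10 coordinate table,
# montage definitions, and the two electrode current-injection models.

# Build the standard spherical 10-10 layout from its geometric construction:
# head frame +x right, +y anterior, +z superior, unit sphere.
#  - midline positions at 10% steps (18 deg) of the nasion-inion arc;
#  - the 10% outer ring at 72 deg inclination, parametrized by azimuth from
#    the front at 18 deg steps;
#  - lateral positions (F3, C3, P3, ...) as great-circle arc midpoints of
#    their midline and ring neighbours (the classical placement rule);
#  - right homologs mirror the left in x.
compute_ten_ten <- function() {
  from_polar <- function(incl_deg, azim_deg) {
    # inclination from +z; azimuth measured from +y (front) toward -x (left)
    th <- incl_deg * pi / 180
    ph <- azim_deg * pi / 180
    c(-sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
  }
  arc_mid <- function(p, q) {
    v <- p + q
    v / sqrt(sum(v^2))
  }
  pos <- list(Cz = c(0, 0, 1))
  midline <- c(
    Fpz = 72, AFz = 54, Fz = 36, FCz = 18, CPz = -18, Pz = -36,
    POz = -54, Oz = -72
  )
  for (nm in names(midline)) {
    a <- midline[[nm]]
    pos[[nm]] <- from_polar(abs(a), if (a >= 0) 0 else 180)
  }
  ring <- c(
    Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90, TP7 = 108,
    P7 = 126, PO7 = 144, O1 = 162
  )
  for (nm in names(ring)) pos[[nm]] <- from_polar(72, ring[[nm]])
  # lateral left positions by the midpoint rule
  pos$F3 <- arc_mid(pos$Fz, pos$F7)
  pos$C3 <- arc_mid(pos$Cz, pos$T7)
  pos$P3 <- arc_mid(pos$Pz, pos$P7)
  pos$AF3 <- arc_mid(pos$AFz, pos$AF7)
  pos$FC3 <- arc_mid(pos$FCz, pos$FT7)
  pos$CP3 <- arc_mid(pos$CPz, pos$TP7)
  pos$PO3 <- arc_mid(pos$POz, pos$PO7)
  # right homologs: mirror x
  left <- setdiff(names(pos), c("Cz", names(midline)))
  for (nm in left) {
    r <- chartr("137", "248", nm) # Fp1->Fp2, F7->F8, F3->F4, ...
    p <- pos[[nm]]
    pos[[r]] <- c(-p[1L], p[2L], p[3L])
  }
  m <- do.call(rbind, pos)
  tibble::tibble(
    label = rownames(m),
    x = round(unname(m[, 1L]), 10),
    y = round(unname(m[, 2L]), 10),
    z = round(unname(m[, 3L]), 10)
  )
}

#' Standard 10-10 electrode directions
#'
#' Unit direction vectors (head frame: +x right, +y anterior, +z superior)
#' for the subset of the 10-10 electrode system used by the montages, read
#' from the versioned CSV asset shipped with the package (falling back to the
#' in-code geometric construction if the asset is absent).
#'
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @export
electrode_positions <- function() {
  path <- system.file("extdata", "ten_ten_positions.csv", package = "tesfield")
  if (nzchar(path) && file.exists(path)) {
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(tibble::as_tibble(tb))
  }
  compute_ten_ten()
}

#' Unit direction of a 10-10 electrode
#'
#' @param label Electrode name, e.g. `"F3"`.
#' @return Length-3 unit vector.
#' @export
#' @examples
#' ten_ten_direction("Cz")
ten_ten_direction <- function(label) {
  tb <- electrode_positions()
  i <- match(label, tb$label)
  if (is.na(i)) stop("unknown 10-10 label: ", label)
  v <- c(tb$x[i], tb$y[i], tb$z[i])
  v / sqrt(sum(v^2))
}

#' The four stimulation montages
#'
#' @return Named list mapping montage name to `c(anode, cathode)` labels.
#' @export
montage_definitions <- function() {
  list(
    "F3-F4" = c("F3", "F4"),
    "F3-P3" = c("F3", "P3"),
    "P3-P4" = c("P3", "P4"),
    "Fp1-P4" = c("Fp1", "P4")
  )
}

# Select outer-boundary facets whose centroids lie within the spherical cap
# of the given area about `direction`. Returns facet rows, areas, and the
# realized cap area.
cap_facets <- function(mesh, direction, area) {
  bf <- boundary_facets(mesh)
  geom <- triangle_geometry(mesh$nodes, bf$tri)
  r_out <- max(sqrt(rowSums(geom$centroid^2)))
  cos_half <- 1 - area / (2 * pi * r_out^2)
  if (cos_half <= -1) stop("patch area exceeds the scalp surface")
  cdir <- geom$centroid / sqrt(rowSums(geom$centroid^2))
  inside <- (cdir %*% direction)[, 1L] >= cos_half
  # only true outer-surface facets (not pad tops etc. at other radii)
  on_outer <- abs(sqrt(rowSums(geom$centroid^2)) - r_out) < 0.25 * r_out
  sel <- which(inside & on_outer)
  if (length(sel) < 20L) {
    stop(sprintf(
      "electrode cap under-resolved: only %d boundary facets inside the cap",
      length(sel)
    ))
  }
  list(
    tri = bf$tri[sel, , drop = FALSE],
    element = bf$element[sel],
    area = geom$area[sel],
    realized_area = sum(geom$area[sel]),
    half_angle = acos(cos_half),
    r_out = r_out
  )
}

#' Place a stimulation montage on a head mesh
#'
#' Places the named anode/cathode pair on the scalp as equal-area spherical
#' caps (a 5 x 5 cm square pad is represented by a cap of the same 25 cm^2
#' area) and defines the injected current model.
#'
#' Two electrode models are available. `PATCH_NEUMANN` (default) applies a
#' uniform inward normal current density `j = I / A_cap` over the cap's
#' boundary facets, with each cap normalized by its own realized (meshed)
#' area so the two fluxes balance exactly. `EXTRUDED_PAD` additionally
#' extrudes a 5 mm saline-gel layer (1 S/m) and a 2 mm conductive pad
#' (29.4 S/m) over each cap and injects the current on the outer pad surface,
#' reproducing the explicit pad-and-gel electrode assembly.
#'
#' @param mesh A [head_mesh()] whose outer boundary is the scalp sphere.
#' @param name Montage name: one of `"F3-F4"`, `"F3-P3"`, `"P3-P4"`,
#'   `"Fp1-P4"`, or a custom `"A-B"` pair of 10-10 labels.
#' @param model `"PATCH_NEUMANN"` or `"EXTRUDED_PAD"`.
#' @param current Injected current in A (anode `+current`, cathode
#'   `-current`); default 2 mA.
#' @param area Patch area in m^2 (default 25 cm^2).
#' @param gel_thickness,pad_thickness Extruded-pad layer thicknesses (m).
#' @return Object of class `montage`: `name`, `model`, `current`,
#'   `anode`/`cathode` (label, direction, realized area), `boundary`
#'   (facet node triples, areas, inward current densities), and `mesh`
#'   (the input mesh, augmented with GEL/PAD elements for `EXTRUDED_PAD`).
#' @export
build_montage <- function(mesh, name, model = c("PATCH_NEUMANN", "EXTRUDED_PAD"),
                          current = 2e-3, area = 25e-4,
                          gel_thickness = 5e-3, pad_thickness = 2e-3) {
  model <- match.arg(model)
  labels <- strsplit(name, "-", fixed = TRUE)[[1L]]
  if (length(labels) != 2L) stop("montage name must be of the form 'A-B'")
  d_a <- ten_ten_direction(labels[1L])
  d_c <- ten_ten_direction(labels[2L])

  cap_a <- cap_facets(mesh, d_a, area)
  cap_c <- cap_facets(mesh, d_c, area)
  sep <- acos(max(-1, min(1, sum(d_a * d_c))))
  if (sep < cap_a$half_angle + cap_c$half_angle) {
    stop("electrode caps overlap for montage ", name)
  }

  if (model == "PATCH_NEUMANN") {
    boundary <- list(
      tri = rbind(cap_a$tri, cap_c$tri),
      area = c(cap_a$area, cap_c$area),
      density = c(
        rep(current / cap_a$realized_area, nrow(cap_a$tri)),
        rep(-current / cap_c$realized_area, nrow(cap_c$tri))
      )
    )
    out_mesh <- mesh
  } else {
    ext <- extrude_pads(mesh, list(cap_a, cap_c), gel_thickness, pad_thickness)
    out_mesh <- ext$mesh
    a_top <- ext$top[[1L]]
    c_top <- ext$top[[2L]]
    boundary <- list(
      tri = rbind(a_top$tri, c_top$tri),
      area = c(a_top$area, c_top$area),
      density = c(
        rep(current / a_top$realized_area, nrow(a_top$tri)),
        rep(-current / c_top$realized_area, nrow(c_top$tri))
      )
    )
  }

  structure(
    list(
      name = name, model = model, current = current,
      anode = list(
        label = labels[1L], direction = d_a,
        realized_area = cap_a$realized_area, half_angle = cap_a$half_angle
      ),
      cathode = list(
        label = labels[2L], direction = d_c,
        realized_area = cap_c$realized_area, half_angle = cap_c$half_angle
      ),
      boundary = boundary,
      mesh = out_mesh
    ),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf(
    "<montage> %s (%s), I = %.1f mA\n  anode %s: cap %.2f cm^2; cathode %s: cap %.2f cm^2\n",
    x$name, x$model, x$current * 1e3,
    x$anode$label, x$anode$realized_area * 1e4,
    x$cathode$label, x$cathode$realized_area * 1e4
  ))
  invisible(x)
}

# Extrude gel + pad element layers over each electrode cap. Uses the same
# monotone-staircase prism split as the layered-sphere builder, keyed on the
# original scalp node ids, so the extrusion is conforming within each pad.
extrude_pads <- function(mesh, caps, gel_thickness, pad_thickness,
                         conductivities = conductivity_defaults()) {
  nodes <- mesh$nodes
  elements <- mesh$elements
  tissue <- mesh$tissue
  sigma <- mesh$conductivity
  if (is.matrix(sigma)) stop("extruded pads require scalar conductivities")
  top_info <- vector("list", length(caps))

  for (ci in seq_along(caps)) {
    cap <- caps[[ci]]
    vids <- sort(unique(as.vector(cap$tri)))
    vdir <- nodes[vids, , drop = FALSE]
    vdir <- vdir / sqrt(rowSums(vdir^2))
    n0 <- nrow(nodes)
    gel_ids <- n0 + seq_along(vids)
    pad_ids <- n0 + length(vids) + seq_along(vids)
    nodes <- rbind(
      nodes,
      nodes[vids, , drop = FALSE] + vdir * gel_thickness,
      nodes[vids, , drop = FALSE] + vdir * (gel_thickness + pad_thickness)
    )
    lookup_gel <- integer(max(vids))
    lookup_gel[vids] <- gel_ids
    lookup_pad <- integer(max(vids))
    lookup_pad[vids] <- pad_ids

    tri_sorted <- sort3_rows(cap$tri)
    layer_tets <- function(base, top) {
      x1 <- base[, 1L]; y1 <- base[, 2L]; z1 <- base[, 3L]
      x2 <- top[, 1L]; y2 <- top[, 2L]; z2 <- top[, 3L]
      rbind(
        cbind(x1, y1, z1, z2),
        cbind(x1, y1, z2, y2),
        cbind(x1, y2, z2, x2)
      )
    }
    gel_tri <- cbind(
      lookup_gel[tri_sorted[, 1L]], lookup_gel[tri_sorted[, 2L]],
      lookup_gel[tri_sorted[, 3L]]
    )
    pad_tri <- cbind(
      lookup_pad[tri_sorted[, 1L]], lookup_pad[tri_sorted[, 2L]],
      lookup_pad[tri_sorted[, 3L]]
    )
    gel_tets <- layer_tets(tri_sorted, gel_tri)
    pad_tets <- layer_tets(gel_tri, pad_tri)
    elements <- rbind(elements, gel_tets, pad_tets)
    tissue <- c(
      tissue, rep("GEL", nrow(gel_tets)), rep("PAD", nrow(pad_tets))
    )
    sigma <- c(
      sigma, rep(conductivities[["GEL"]], nrow(gel_tets)),
      rep(conductivities[["PAD"]], nrow(pad_tets))
    )
    top_geom <- triangle_geometry(nodes, pad_tri)
    top_info[[ci]] <- list(
      tri = pad_tri, area = top_geom$area,
      realized_area = sum(top_geom$area)
    )
  }
  list(
    mesh = head_mesh(nodes, elements, tissue, conductivity = sigma),
    top = top_info
  )
}
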