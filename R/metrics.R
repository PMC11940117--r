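# Outcome metrics of a field solution (percentile peak, focality, ROI
# amplitudes) and anatomical predictors (relative tissue volumes, local
# under-electrode thicknesses).

#' Volume-weighted empirical percentile
#'
#' Lower-step convention: the smallest observed value `v` such that the
#' weight fraction of observations with value `<= v` is at least `q/100`.
#' With equal weights this reduces to the ordinary empirical quantile of
#' type 1.
#'
#' @param values Numeric vector (e.g. per-element field magnitudes).
#' @param weights Positive weights (e.g. element volumes); equal by default.
#' @param q Percentile in (0, 100).
#' @return The threshold value.
#' @export
#' @examples
#' weighted_percentile(1:100, q = 99)
weighted_percentile <- function(values, weights = NULL, q) {
  if (length(values) == 0L) stop("empty input")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) stop("weights/values length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  if (q <= 0 || q >= 100) stop("q must be in (0, 100)")
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  values[o][which(cw >= q / 100 - 1e-12)[1L]]
}

#' Compute field outcome metrics
#'
#' The peak field `peak99` is the volume-weighted 99th percentile of the
#' element field magnitude over grey matter; the focality `focality75` is the
#' grey-matter volume (cm^3) whose magnitude strictly exceeds the
#' volume-weighted 75th percentile. Region-of-interest amplitudes report the
#' 99th percentile and the volume-weighted mean within each ROI's element
#' set.
#'
#' @param field A [compute_efield()] result.
#' @param mesh The [head_mesh()] the field was solved on.
#' @param rois Optional named list of element-index vectors
#'   ([define_phantom_rois()]).
#' @param weighting `"volume"` (default) or `"count"`: weighting of the
#'   percentiles (count-weighting is exposed for sensitivity analysis).
#' @return A one-row tibble: `peak99` (V/m), `focality75` (cm^3),
#'   `gm_volume_cm3`, and per ROI `roi_<name>_p99` / `roi_<name>_mean` (V/m).
#' @export
compute_field_metrics <- function(field, mesh, rois = NULL,
                                  weighting = c("volume", "count")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(field, "field_solution"), inherits(mesh, "head_mesh"))
  if (length(field$magnitude) != nrow(mesh$elements)) {
    stop("field and mesh are inconsistent")
  }
  gm <- which(mesh$tissue == "GM")
  if (length(gm) == 0L) stop("mesh has no GM elements")
  mag <- field$magnitude[gm]
  w <- if (weighting == "volume") mesh$volume[gm] else rep(1, length(gm))
  peak99 <- weighted_percentile(mag, w, 99)
  thr75 <- weighted_percentile(mag, w, 75)
  focality75 <- sum(mesh$volume[gm][mag > thr75]) * 1e6

  out <- tibble::tibble(
    peak99 = peak99,
    focality75 = focality75,
    gm_volume_cm3 = sum(mesh$volume[gm]) * 1e6
  )
  for (nm in names(rois)) {
    ids <- rois[[nm]]
    rmag <- field$magnitude[ids]
    rw <- if (weighting == "volume") mesh$volume[ids] else rep(1, length(ids))
    out[[paste0("roi_", nm, "_p99")]] <- weighted_percentile(rmag, rw, 99)
    out[[paste0("roi_", nm, "_mean")]] <- sum(rmag * rw) / sum(rw)
  }
  out
}

#' Relative tissue volumes (global anatomical parameters)
#'
#' Total intracranial volume (TIV) is defined as the contents of the inner
#' skull surface: CSF + GM + WM + ventricle. Each tissue's relative volume is
#' its volume divided by TIV, so the four relative volumes partition 1.
#'
#' @param mesh A [head_mesh()].
#' @return One-row tibble: `tiv_cm3`, `rel_gm`, `rel_wm`, `rel_csf`,
#'   `rel_vent`.
#' @export
relative_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "head_mesh"))
  vol_of <- function(lab) sum(mesh$volume[mesh$tissue == lab])
  v <- c(
    CSF = vol_of("CSF"), GM = vol_of("GM"), WM = vol_of("WM"),
    VENTRICLE = vol_of("VENTRICLE")
  )
  tiv <- sum(v)
  if (tiv == 0) stop("TIV is zero: no intracranial tissue in the mesh")
  tibble::tibble(
    tiv_cm3 = tiv * 1e6,
    rel_gm = v[["GM"]] / tiv,
    rel_wm = v[["WM"]] / tiv,
    rel_csf = v[["CSF"]] / tiv,
    rel_vent = v[["VENTRICLE"]] / tiv
  )
}

#' Local under-electrode layer thicknesses and electrode-to-cortex distance
#'
#' Casts a ray from the scalp point under the electrode center toward the
#' head center and measures the ray length inside the scalp, skull and CSF
#' layers. The electrode-to-cortex distance is their sum. Accepts either a
#' [phantom_spec()] (exact layer differences) or a [head_mesh()] (ray casting
#' against the tissue-interface facets), which agree to within the mesh
#' resolution on a layered sphere.
#'
#' @param x A `phantom_spec` or `head_mesh`.
#' @param direction Unit vector toward the electrode center.
#' @return One-row tibble: `scalp_mm`, `skull_mm`, `csf_mm`, `distance_mm`.
#' @export
local_thickness_profile <- function(x, direction) {
  UseMethod("local_thickness_profile")
}

#' @export
local_thickness_profile.phantom_spec <- function(x, direction) {
  th <- phantom_thicknesses_mm(x)
  tibble::tibble(
    scalp_mm = th[["SCALP"]],
    skull_mm = th[["SKULL"]],
    csf_mm = th[["CSF"]],
    distance_mm = th[["SCALP"]] + th[["SKULL"]] + th[["CSF"]]
  )
}

#' @export
local_thickness_profile.head_mesh <- function(x, direction) {
  direction <- direction / sqrt(sum(direction^2))
  crossings <- ray_interface_crossings(x, direction)
  outer_r <- crossings$outer_radius
  get_r <- function(a, b) {
    pair <- paste(min(a, b), max(a, b), sep = "|") # pairs are stored sorted
    i <- match(pair, crossings$pairs$pair)
    if (is.na(i)) stop("ray failed to cross the ", a, "/", b, " interface")
    crossings$pairs$r[i]
  }
  r1 <- get_r("SCALP", "SKULL")
  r2 <- get_r("SKULL", "CSF")
  r3 <- get_r("CSF", "GM")
  tibble::tibble(
    scalp_mm = (outer_r - r1) * 1e3,
    skull_mm = (r1 - r2) * 1e3,
    csf_mm = (r2 - r3) * 1e3,
    distance_mm = (outer_r - r3) * 1e3
  )
}

# Intersect the radial ray along `direction` with every facet separating two
# different tissue labels; returns the crossing radius per interface pair.
ray_interface_crossings <- function(mesh, direction) {
  el <- mesh$elements
  m <- nrow(el)
  faces <- rbind(
    el[, c(2L, 3L, 4L)], el[, c(1L, 4L, 3L)],
    el[, c(1L, 2L, 4L)], el[, c(1L, 3L, 2L)]
  )
  owner <- rep(seq_len(m), times = 4L)
  key <- face_key(faces, nrow(mesh$nodes))
  o <- order(key)
  key_s <- key[o]
  dupe <- key_s[-1L] == key_s[-length(key_s)]
  first <- o[c(dupe, FALSE)]
  second <- o[c(FALSE, dupe)]
  lab1 <- mesh$tissue[owner[first]]
  lab2 <- mesh$tissue[owner[second]]
  differs <- lab1 != lab2
  tri <- faces[first[differs], , drop = FALSE]
  pr <- cbind(pmin(lab1[differs], lab2[differs]), pmax(lab1[differs], lab2[differs]))

  # Moeller-Trumbore ray/triangle intersection from the origin outward along
  # -direction? The ray runs from outside toward the center: parametrize
  # p(t) = t * direction, t in (0, R]; intersect with each interface facet.
  a <- mesh$nodes[tri[, 1L], , drop = FALSE]
  b <- mesh$nodes[tri[, 2L], , drop = FALSE]
  c_ <- mesh$nodes[tri[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  d <- matrix(direction, nrow(a), 3L, byrow = TRUE)
  pvec <- cbind(
    d[, 2L] * e2[, 3L] - d[, 3L] * e2[, 2L],
    d[, 3L] * e2[, 1L] - d[, 1L] * e2[, 3L],
    d[, 1L] * e2[, 2L] - d[, 2L] * e2[, 1L]
  )
  det <- rowSums(e1 * pvec)
  tvec <- -a # origin (0,0,0) minus a
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(
    tvec[, 2L] * e1[, 3L] - tvec[, 3L] * e1[, 2L],
    tvec[, 3L] * e1[, 1L] - tvec[, 1L] * e1[, 3L],
    tvec[, 1L] * e1[, 2L] - tvec[, 2L] * e1[, 1L]
  )
  v <- rowSums(d * qvec) / det
  t_ <- rowSums(e2 * qvec) / det
  eps <- 1e-10
  hit <- abs(det) > 1e-300 & u >= -eps & v >= -eps & (u + v) <= 1 + eps & t_ > 0
  if (!any(hit)) stop("ray does not intersect any tissue interface")
  pair <- paste(pr[hit, 1L], pr[hit, 2L], sep = "|")
  r <- t_[hit]
  pairs <- tibble::tibble(pair = pair, r = r)
  pairs <- dplyr::summarise(
    dplyr::group_by(pairs, pair),
    r = stats::median(r), .groups = "drop"
  )

  # outer scalp radius along the ray
  bf <- boundary_facets(mesh)
  geom <- triangle_geometry(mesh$nodes, bf$tri)
  outer_radius <- max(sqrt(rowSums(geom$centroid^2)))
  list(pairs = pairs, outer_radius = outer_radius)
}
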