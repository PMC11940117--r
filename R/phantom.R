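# Synthetic aging-cohort phantom generator: layered-sphere specifications
# with age-dependent layer thicknesses.

#' Specify a layered spherical head phantom
#'
#' @param r_scalp,r_skull,r_csf,r_gm,r_wm Outer radius of each layer in
#'   meters, strictly decreasing. Defaults follow the classical four-sphere
#'   head-model radii (92/86/80/78 mm) with a 60 mm white-matter core.
#' @param r_vent Ventricle (CSF-filled core) radius in meters; `0` omits the
#'   ventricle compartment.
#' @return Object of class `phantom_spec` with `radii` and `labels` ordered
#'   outside-in.
#' @export
#' @examples
#' phantom_spec()
phantom_spec <- function(r_scalp = 0.092, r_skull = 0.086, r_csf = 0.080,
                         r_gm = 0.078, r_wm = 0.060, r_vent = 0) {
  radii <- c(r_scalp, r_skull, r_csf, r_gm, r_wm)
  labels <- c("SCALP", "SKULL", "CSF", "GM", "WM")
  if (r_vent > 0) {
    if (r_vent >= r_wm) stop("ventricle radius must be smaller than the WM radius")
    radii <- c(radii, r_vent)
    labels <- c(labels, "VENTRICLE")
  }
  if (any(diff(radii) >= 0)) stop("layer radii must be strictly decreasing")
  if (any(radii <= 0)) stop("radii must be positive")
  structure(list(radii = radii, labels = labels), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  th <- -diff(c(x$radii, 0))
  for (i in seq_along(x$radii)) {
    cat(sprintf(
      "  %-9s R = %5.1f mm  (thickness %.1f mm)\n",
      x$labels[i], x$radii[i] * 1e3, th[i] * 1e3
    ))
  }
  invisible(x)
}

# Layer thicknesses in mm implied by a phantom_spec (named, outside-in).
phantom_thicknesses_mm <- function(spec) {
  th <- -diff(c(spec$radii, 0)) * 1e3
  names(th) <- spec$labels
  th
}

#' Default anatomical age trajectories
#'
#' Piecewise-linear trajectories of layer thickness (mm) against age (years)
#' over the adult range 18-88, one per anatomical quantity, each with a
#' between-subject Gaussian noise SD. The default shapes encode the
#' qualitative adult-lifespan picture from the structural-aging literature:
#' grey matter thins steadily; skull thickness follows an inverted U peaking
#' near age 60; CSF thickness rises after age 20; scalp thickness is stable
#' until about 60 and declines thereafter; the ventricle radius grows with a
#' steeper slope after 60.
#'
#' @return Object of class `tissue_trajectories`: a named list with, per
#'   quantity (`scalp`, `skull`, `csf`, `gm`, `vent`), a `knots` matrix
#'   (columns age, value in mm) and a noise `sd` (mm).
#' @export
default_trajectories <- function() {
  traj <- list(
    scalp = list(
      knots = cbind(age = c(18, 60, 80, 88), value = c(6.0, 6.0, 5.75, 5.1)),
      sd = 0.3
    ),
    skull = list(
      knots = cbind(age = c(18, 60, 80, 88), value = c(5.5, 7.0, 6.8, 5.8)),
      sd = 0.4
    ),
    csf = list(
      knots = cbind(age = c(18, 20, 80, 88), value = c(2.0, 2.0, 4.0, 4.6)),
      sd = 0.3
    ),
    gm = list(
      knots = cbind(age = c(18, 50, 70, 88), value = c(19.0, 17.8, 17.2, 16.2)),
      sd = 0.5
    ),
    vent = list(
      knots = cbind(age = c(18, 60, 88), value = c(10.0, 13.0, 18.0)),
      sd = 1.0
    )
  )
  structure(traj, class = "tissue_trajectories")
}

# Evaluate one piecewise-linear trajectory at given ages (constant
# extrapolation beyond the knot range).
eval_trajectory <- function(traj_q, age) {
  stats::approx(traj_q$knots[, "age"], traj_q$knots[, "value"],
    xout = age, rule = 2
  )$y
}

#' Realize the phantom anatomy of one subject at a given age
#'
#' Evaluates each thickness trajectory at `age`, adds Gaussian between-subject
#' noise (truncated below at 0.5 mm so no layer degenerates), and converts
#' thicknesses to layer radii inward from a fixed outer scalp radius.
#'
#' @param age Age in years, within 18-88.
#' @param traj A [default_trajectories()]-style object.
#' @param r_scalp Outer scalp radius in meters (fixed across ages).
#' @param ventricle Include a ventricle core?
#' @return A [phantom_spec()].
#' @details Draws are resampled (up to 10 times) if the noisy thicknesses
#'   produce non-decreasing radii (e.g. a ventricle larger than the WM core);
#'   persistent failure is an error. With all noise SDs zero the function is
#'   deterministic in `age`.
#' @export
anatomy_at_age <- function(age, traj = default_trajectories(),
                           r_scalp = 0.092, ventricle = TRUE) {
  if (age < 18 || age > 88.92) stop("age must be within [18, 88.92]")
  for (attempt in 1:10) {
    th <- vapply(traj, function(q) {
      max(0.5, eval_trajectory(q, age) + stats::rnorm(1L, 0, q$sd))
    }, numeric(1L))
    r_skull <- r_scalp - th[["scalp"]] / 1e3
    r_csf <- r_skull - th[["skull"]] / 1e3
    r_gm <- r_csf - th[["csf"]] / 1e3
    r_wm <- r_gm - th[["gm"]] / 1e3
    r_vent <- if (ventricle) th[["vent"]] / 1e3 else 0
    ok <- r_scalp > r_skull && r_skull > r_csf && r_csf > r_gm &&
      r_gm > r_wm && r_wm > r_vent && r_wm > 0
    if (ok) {
      return(phantom_spec(r_scalp, r_skull, r_csf, r_gm, r_wm, r_vent))
    }
  }
  stop("could not realize a valid phantom after 10 resampling attempts")
}

#' Age-group bins used for decade grouping
#'
#' Eight bins spanning adulthood: 18-20, then decades 21-30 through 71-80,
#' and 81-88.
#'
#' @return A tibble with `group`, `lo`, `hi` (inclusive integer age parts).
#' @export
age_group_bins <- function() {
  tibble::tibble(
    group = c("18-20", "21-30", "31-40", "41-50", "51-60", "61-70", "71-80", "81-88"),
    lo = c(18, 21, 31, 41, 51, 61, 71, 81),
    hi = c(20, 30, 40, 50, 60, 70, 80, 88)
  )
}

#' Specify a synthetic cohort
#'
#' @param n_per_group Integer vector of subjects per age bin, recycled to the
#'   number of bins.
#' @param bins Age-bin table as from [age_group_bins()].
#' @param traj Tissue trajectories ([default_trajectories()]).
#' @param r_scalp Outer scalp radius (m).
#' @param ventricle Include ventricle cores?
#' @param seed Master seed; all per-subject seeds derive from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20L, bins = age_group_bins(),
                        traj = default_trajectories(), r_scalp = 0.092,
                        ventricle = TRUE, seed = 1L) {
  n_per_group <- rep_len(as.integer(n_per_group), nrow(bins))
  if (any(n_per_group < 1L)) stop("need at least one subject per group")
  if (any(bins$lo[-1L] <= bins$hi[-nrow(bins)])) {
    stop("age bins must be ordered and non-overlapping")
  }
  structure(
    list(
      n_per_group = n_per_group, bins = bins, traj = traj,
      r_scalp = r_scalp, ventricle = ventricle, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Deterministic per-subject seed stream: a simple 32-bit LCG step keyed by
# the master seed and the subject counter (order-independent).
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 69069 + counter * 12345) %% 2147483647)
}

#' Sample a synthetic cohort
#'
#' Draws subject ages uniformly within each age bin and realizes each
#' subject's phantom anatomy from the trajectories. Fully deterministic given
#' the master seed; per-subject seeds are derived by counter so results do not
#' depend on evaluation order.
#'
#' @param cohort A [cohort_spec()].
#' @return A tibble with one row per subject: `subject`, `age`, `group`,
#'   per-layer realized thicknesses in mm (`scalp_mm`, `skull_mm`, `csf_mm`,
#'   `gm_mm`, `vent_mm`), the subject `seed`, and a list-column `spec` of
#'   [phantom_spec()] objects.
#' @export
sample_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  bins <- cohort$bins
  counter <- 0L
  rows <- list()
  for (g in seq_len(nrow(bins))) {
    for (i in seq_len(cohort$n_per_group[g])) {
      counter <- counter + 1L
      sseed <- derive_seed(cohort$seed, counter)
      spec <- local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(
          if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE
        )
        set.seed(sseed)
        # uniform over the bin's age span, capped at the adult-range maximum
        age <- stats::runif(1L, bins$lo[g], min(bins$hi[g] + 0.999, 88.92))
        list(
          age = age,
          spec = anatomy_at_age(age, cohort$traj, cohort$r_scalp, cohort$ventricle)
        )
      })
      th <- phantom_thicknesses_mm(spec$spec)
      rows[[counter]] <- tibble::tibble(
        subject = sprintf("S%03d", counter),
        age = spec$age,
        group = bins$group[g],
        scalp_mm = th[["SCALP"]],
        skull_mm = th[["SKULL"]],
        csf_mm = th[["CSF"]],
        gm_mm = th[["GM"]],
        vent_mm = if ("VENTRICLE" %in% names(th)) unname(th["VENTRICLE"]) else 0,
        seed = sseed,
        spec = list(spec$spec)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Define geometric region-of-interest analogs on a phantom mesh
#'
#' Three ROIs mimicking the anatomical placement of cognitive-task targets on
#' a spherical head: a ventromedial-prefrontal analog (`VMPFC_A`, grey-matter
#' elements inside an anterior-inferior spherical cone), a posterior-parietal
#' analog (`PPC_A`, posterior-superior cone), and a deep left hippocampal
#' analog (`HIPP_A`, a 10 mm ball at 0.55 of the grey-matter radius on the
#' left, intersected with brain tissue). Head frame: +x right, +y anterior,
#' +z superior.
#'
#' @param mesh A [head_mesh()] with GM (and WM) labels.
#' @param half_angle_deg Cone half-angle for the two cortical ROIs (degrees).
#' @param hipp_radius Radius of the hippocampal ball in meters.
#' @return Named list of integer element-index vectors
#'   (`VMPFC_A`, `PPC_A`, `HIPP_A`).
#' @export
define_phantom_rois <- function(mesh, half_angle_deg = 25, hipp_radius = 0.010) {
  stopifnot(inherits(mesh, "head_mesh"))
  if (!any(mesh$tissue == "GM")) stop("mesh has no GM elements")
  cen <- tet_centroids(mesh)
  r <- sqrt(rowSums(cen^2))
  dir <- cen / r
  gm <- mesh$tissue == "GM"
  brain <- mesh$tissue %in% c("GM", "WM")
  r_gm <- max(r[gm]) # outer GM radius (approximately the GM shell radius)

  axis_vmpfc <- c(0, 0.94, -0.34)
  axis_vmpfc <- axis_vmpfc / sqrt(sum(axis_vmpfc^2))
  axis_ppc <- c(0, -0.64, 0.77)
  axis_ppc <- axis_ppc / sqrt(sum(axis_ppc^2))
  cos_ha <- cos(half_angle_deg * pi / 180)

  vmpfc <- which(gm & (dir %*% axis_vmpfc)[, 1L] >= cos_ha)
  ppc <- which(gm & (dir %*% axis_ppc)[, 1L] >= cos_ha)
  hipp_center <- c(-0.55 * r_gm, 0, 0)
  d2 <- (cen[, 1L] - hipp_center[1L])^2 + cen[, 2L]^2 + cen[, 3L]^2
  hipp <- which(brain & d2 <= hipp_radius^2)

  rois <- list(VMPFC_A = vmpfc, PPC_A = ppc, HIPP_A = hipp)
  empty <- names(rois)[vapply(rois, length, integer(1L)) == 0L]
  if (length(empty) > 0L) {
    stop(
      "empty ROI at this mesh resolution: ",
      paste(empty, collapse = ", ")
    )
  }
  rois
}
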