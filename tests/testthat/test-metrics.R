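test_that("weighted percentile follows the lower-step convention", {
  expect_equal(weighted_percentile(rep(3.7, 50L), q = 42), 3.7)
  expect_equal(weighted_percentile(1:100, q = 99), 99)
  expect_equal(weighted_percentile(1:100, q = 75), 75)
  # permutation invariance
  set.seed(3)
  v <- stats::runif(500L)
  w <- stats::runif(500L, 0.1, 2)
  p <- sample.int(500L)
  expect_identical(
    weighted_percentile(v, w, 75),
    weighted_percentile(v[p], w[p], 75)
  )
  expect_error(weighted_percentile(numeric(0), q = 50), "empty")
  expect_error(weighted_percentile(1:3, c(1, -1, 1), 50), "positive")
  expect_error(weighted_percentile(1:3, q = 100), "q")
})

test_that("weighted percentiles match the brute-force sort-and-scan oracle", {
  set.seed(42)
  for (rep in 1:3) {
    v <- stats::rlnorm(1e4)
    w <- stats::runif(1e4, 0.2, 3)
    for (q in c(50, 75, 99)) {
      expect_identical(
        weighted_percentile(v, w, q),
        brute_weighted_percentile(v, w, q)
      )
    }
  }
})

test_that("field metrics handle uniform, stepped and scaled fields", {
  mesh <- smoke_mesh()
  gm <- which(mesh$tissue == "GM")
  gm_vol <- sum(mesh$volume[gm])
  mk_field <- function(mag) {
    structure(
      list(
        phi = NULL, E = NULL,
        magnitude = mag, diagnostics = NULL
      ),
      class = "field_solution"
    )
  }
  # uniform field: peak99 = c, focality75 = 0 (nothing strictly above)
  mag <- numeric(nrow(mesh$elements))
  mag[gm] <- 0.31
  fm <- compute_field_metrics(mk_field(mag), mesh)
  expect_equal(fm$peak99, 0.31)
  expect_equal(fm$focality75, 0)

  # constructed field: exactly ~20% of GM volume at 2, rest at 1
  o <- order(mesh$volume[gm])
  cum <- cumsum(mesh$volume[gm][o]) / gm_vol
  top <- gm[o][cum > 0.8]
  mag2 <- numeric(nrow(mesh$elements))
  mag2[gm] <- 1
  mag2[top] <- 2
  fm2 <- compute_field_metrics(mk_field(mag2), mesh)
  top_vol <- sum(mesh$volume[top]) * 1e6
  expect_equal(fm2$focality75, top_vol, tolerance = 1e-12)

  # scaling the field: peak99 triples, focality unchanged
  fm3 <- compute_field_metrics(mk_field(mag2 * 3), mesh)
  expect_equal(fm3$peak99, 3 * fm2$peak99)
  expect_equal(fm3$focality75, fm2$focality75)

  # focality bound: never above 25% of GM volume plus one element
  sf <- smoke_field()
  fm4 <- compute_field_metrics(sf$field, mesh)
  expect_lte(
    fm4$focality75,
    0.25 * gm_vol * 1e6 + max(mesh$volume[gm]) * 1e6
  )
  expect_gte(fm4$peak99, 0)
})

test_that("ROI amplitudes reflect electrode placement", {
  sf <- smoke_field()
  rois <- define_phantom_rois(sf$mesh)
  fm <- compute_field_metrics(sf$field, sf$mesh, rois)
  # F3-F4 sits over the frontal cortex: the prefrontal analog sees a much
  # stronger field than the deep hippocampal analog
  expect_gt(fm$roi_VMPFC_A_p99, fm$roi_HIPP_A_p99)
  expect_gt(fm$roi_VMPFC_A_p99, fm$roi_VMPFC_A_mean)
})

test_that("relative volumes partition the intracranial space", {
  mesh <- smoke_mesh() # no ventricle: GM + WM + CSF partition TIV
  rv <- relative_volumes(mesh)
  expect_equal(rv$rel_gm + rv$rel_wm + rv$rel_csf, 1, tolerance = 1e-12)
  expect_equal(rv$rel_vent, 0)

  # closed-form check of rel(GM) on the exact shells
  spec <- phantom_spec()
  shells <- shell_volumes_cm3(spec)
  tiv <- sum(shells[c("CSF", "GM", "WM")])
  expect_lt(abs(rv$rel_gm - shells[["GM"]] / tiv), 0.02 * shells[["GM"]] / tiv)

  # thickening CSF at fixed other radii raises rel(CSF)
  thin <- build_layered_sphere(
    phantom_spec(r_csf = 0.080, r_gm = 0.078),
    subdiv = 2L, h = 4e-3
  )
  thick <- build_layered_sphere(
    phantom_spec(r_csf = 0.080, r_gm = 0.074),
    subdiv = 2L, h = 4e-3
  )
  expect_gt(relative_volumes(thick)$rel_csf, relative_volumes(thin)$rel_csf)

  # ventricle counts toward TIV
  vent <- build_layered_sphere(
    phantom_spec(r_vent = 0.015),
    subdiv = 2L, h = 4e-3
  )
  rvv <- relative_volumes(vent)
  expect_equal(
    rvv$rel_gm + rvv$rel_wm + rvv$rel_csf + rvv$rel_vent, 1,
    tolerance = 1e-12
  )
  expect_gt(rvv$rel_vent, 0)
})

test_that("local thickness profiles agree between spec geometry and mesh ray casting", {
  spec <- phantom_spec()
  d <- ten_ten_direction("F3")
  th_spec <- local_thickness_profile(spec, d)
  expect_equal(th_spec$scalp_mm, 6)
  expect_equal(th_spec$skull_mm, 6)
  expect_equal(th_spec$csf_mm, 2)
  expect_identical(
    th_spec$distance_mm,
    th_spec$scalp_mm + th_spec$skull_mm + th_spec$csf_mm
  )
  th_mesh <- local_thickness_profile(smoke_mesh(), d)
  # mesh-level ray casting agrees within the mesh resolution
  for (col in names(th_spec)) {
    expect_lt(abs(th_mesh[[col]] - th_spec[[col]]), 4) # h = 4 mm mesh
    expect_lt(abs(th_mesh[[col]] - th_spec[[col]]) / max(th_spec[[col]], 1), 0.25)
  }
})
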