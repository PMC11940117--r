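test_that("P1 stiffness of a regular tetrahedron matches the closed form", {
  # for edge a and sigma = 1: K_ii = a sqrt(2)/8, K_ij = -a sqrt(2)/24
  a <- 0.013
  mesh <- regular_tet_mesh(a)
  mesh$conductivity <- 1
  sys <- assemble_system(mesh)
  K <- as.matrix(sys$K)
  expected <- matrix(-a * sqrt(2) / 24, 4L, 4L)
  diag(expected) <- a * sqrt(2) / 8
  expect_equal(K, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("assembled system has the constants in its null space and balanced load", {
  sf <- smoke_field()
  sys <- assemble_system(sf$mesh, sf$montage)
  scale <- max(abs(sys$K@x))
  expect_lt(max(abs(Matrix::rowSums(sys$K))) / scale, 1e-12)
  expect_lt(abs(sum(sys$b)), 1e-15 * sf$montage$current)
})

test_that("solver respects homogeneity, conductivity scaling and dose linearity", {
  mesh <- smoke_mesh()
  mon <- build_montage(mesh, "F3-F4")
  sys <- assemble_system(mesh, mon)
  # zero load -> identically zero potential
  sys0 <- sys
  sys0$b <- numeric(sys$n_nodes)
  expect_identical(solve_potential(sys0)$phi, numeric(sys$n_nodes))

  phi <- smoke_field()$field$phi
  # doubling all conductivities halves the potential
  mesh2 <- mesh
  mesh2$conductivity <- mesh$conductivity * 2
  phi_half <- solve_potential(assemble_system(mesh2, mon))$phi
  expect_lt(max(abs(2 * phi_half - phi)) / max(abs(phi)), 1e-9)
  # doubling the current doubles the potential
  mon2 <- build_montage(mesh, "F3-F4", current = 4e-3)
  phi_double <- solve_potential(assemble_system(mesh, mon2))$phi
  expect_lt(max(abs(phi_double - 2 * phi)) / max(abs(phi)), 1e-9)
  # mean-zero gauge
  expect_lt(abs(mean(phi)), 1e-12 * max(abs(phi)))
})

test_that("imposed linear potential reproduces a constant unit field exactly", {
  mesh <- cube_mesh()
  fld <- compute_efield(mesh, -mesh$nodes[, 1L])
  expect_equal(
    fld$E, matrix(rep(c(1, 0, 0), each = 6L), 6L, 3L),
    tolerance = 1e-13, ignore_attr = TRUE
  )
  expect_equal(fld$magnitude, rep(1, 6L), tolerance = 1e-13)
})

test_that("swapping anode and cathode negates the field everywhere", {
  sf <- smoke_field()
  mon_rev <- build_montage(sf$mesh, "F4-F3")
  fld_rev <- solve_montage(sf$mesh, mon_rev)
  expect_lt(
    max(abs(fld_rev$E + sf$field$E)) / max(abs(sf$field$E)), 1e-9
  )
  expect_equal(fld_rev$magnitude, sf$field$magnitude, tolerance = 1e-9)
})

test_that("synthetic WM anisotropy preserves the geometric mean and the isotropic limit", {
  mesh <- smoke_mesh()
  iso <- tensorize_wm(mesh, rho = 1)
  wm <- mesh$tissue == "WM"
  expect_equal(iso$conductivity[wm, 1L], mesh$conductivity[wm], tolerance = 1e-12)
  expect_true(all(abs(iso$conductivity[wm, 4:6]) < 1e-15))
  # isotropic-limit solution identical to the scalar run
  mon <- build_montage(mesh, "F3-F4")
  phi_s <- smoke_field()$field$phi
  phi_t <- solve_potential(assemble_system(iso, mon))$phi
  expect_lt(max(abs(phi_t - phi_s)) / max(abs(phi_s)), 1e-10)

  for (rho in c(2, 10)) {
    tens <- tensorize_wm(mesh, rho = rho)
    tw <- tens$conductivity[wm, , drop = FALSE]
    gmean <- apply(tw, 1L, function(row) {
      m <- matrix(
        c(
          row[1L], row[4L], row[5L], row[4L], row[2L], row[6L],
          row[5L], row[6L], row[3L]
        ), 3L, 3L
      )
      prod(eigen(m, symmetric = TRUE, only.values = TRUE)$values)^(1 / 3)
    })
    expect_equal(
      gmean[1:25], rep(0.126, 25L),
      tolerance = 1e-9
    )
    expect_true(all(tesfield:::tensor_is_spd(tw)))
  }
  expect_error(tensorize_wm(mesh, rho = 0.5), "rho")
})

test_that("anisotropy changes the peak while conservation still holds", {
  mesh <- smoke_mesh()
  mon <- build_montage(mesh, "F3-F4")
  tens <- tensorize_wm(mesh, rho = 10)
  fld_t <- solve_montage(tens, mon)
  fld_s <- smoke_field()$field
  gm <- which(mesh$tissue == "GM")
  p_s <- weighted_percentile(fld_s$magnitude[gm], mesh$volume[gm], 99)
  p_t <- weighted_percentile(fld_t$magnitude[gm], mesh$volume[gm], 99)
  expect_false(isTRUE(all.equal(p_s, p_t, tolerance = 1e-6)))
  # closed-surface flux through the CSF/GM interface stays ~0 (conservation)
  flux <- interface_current(tens, fld_t, 0.078)
  expect_lt(abs(flux) / mon$current, 0.01)
})
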