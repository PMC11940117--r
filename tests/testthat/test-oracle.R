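test_that("cap source expansion balances, alternates for antipodal pairs, and converges", {
  mk <- function(L) {
    sphere_model(
      radii = 0.09, sigma = 1,
      caps = list(
        list(direction = c(0, 0, 1), area = 25e-4, current = 2e-3),
        list(direction = c(0, 0, -1), area = 25e-4, current = -2e-3)
      ),
      L = L
    )
  }
  model <- mk(100L)
  src <- cap_source_coefficients(model)
  # net flux of the reconstructed density: only degree 0 survives the
  # surface integral, and the two caps' degree-0 terms cancel
  net <- sum(vapply(src, function(s) s$g[1L], numeric(1L)))
  expect_lt(abs(net) * 4 * pi * 0.09^2, 1e-12 * 2e-3)

  # antipodal caps: potential is odd under point reflection
  pts <- matrix(c(
    0.03, 0.01, 0.05,
    -0.03, -0.01, -0.05,
    0.02, -0.04, 0.01,
    -0.02, 0.04, -0.01
  ), ncol = 3L, byrow = TRUE)
  phi <- sphere_potential(model, pts)
  expect_equal(phi[c(2L, 4L)], -phi[c(1L, 3L)], tolerance = 1e-10)

  # L2 error of the reconstructed density against the cap indicator
  # decreases over L = 25, 50, 100
  u <- seq(-1, 1, length.out = 4001L)[-c(1L, 4001L)]
  ca <- cos(model$caps[[1L]]$half_angle)
  j0 <- src[[1L]]$j0
  exact <- ifelse(u >= ca, j0, 0) + ifelse(-u >= ca, -j0, 0)
  l2_at <- function(L) {
    m <- mk(L)
    rec <- reconstruct_cap_density(m, u, 1L) + reconstruct_cap_density(m, -u, 2L)
    sqrt(mean((rec - exact)^2))
  }
  errs <- c(l2_at(25L), l2_at(50L), l2_at(100L))
  expect_true(all(diff(errs) < 0))
})

test_that("homogeneous multilayer model collapses to the single-sphere closed form", {
  caps <- list(
    list(direction = c(0, 1, 0), area = 25e-4, current = 2e-3),
    list(direction = c(1, 0, 0), area = 25e-4, current = -2e-3)
  )
  multi <- sphere_model(
    radii = c(0.092, 0.086, 0.08, 0.078, 0.06),
    sigma = rep(0.3, 5L), caps = caps, L = 60L
  )
  single <- sphere_model(radii = 0.092, sigma = 0.3, caps = caps, L = 60L)
  set.seed(1)
  pts <- matrix(stats::rnorm(60L), ncol = 3L)
  pts <- pts / sqrt(rowSums(pts^2)) * stats::runif(20L, 0.01, 0.088)
  expect_equal(
    sphere_potential(multi, pts), sphere_potential(single, pts),
    tolerance = 1e-12
  )
  expect_lt(oracle_continuity_residual(multi), 1e-10)
})

test_that("analytic solution is mirror-symmetric about the montage plane", {
  model <- default_sphere_model(L = 80L)
  # F3-F4 montage: mirror symmetry in x
  pts <- matrix(c(
    0.02, 0.03, 0.05,
    -0.02, 0.03, 0.05,
    0.04, -0.02, 0.01,
    -0.04, -0.02, 0.01
  ), ncol = 3L, byrow = TRUE)
  phi <- sphere_potential(model, pts)
  # anode at F3 (x < 0), cathode at F4: mirrored points have opposite sign
  expect_equal(phi[c(2L, 4L)], -phi[c(1L, 3L)], tolerance = 1e-9)
  E <- sphere_efield(model, pts)
  expect_equal(abs(E[2L, ]), abs(E[1L, ]), tolerance = 1e-9)
})

test_that("series gradient matches central finite differences of the potential", {
  model <- default_sphere_model(L = 80L)
  set.seed(7)
  pts <- matrix(stats::rnorm(45L), ncol = 3L)
  pts <- pts / sqrt(rowSums(pts^2)) * stats::runif(15L, 0.02, 0.075)
  E <- sphere_efield(model, pts)
  hstep <- 1e-6
  for (d in 1:3) {
    dp <- matrix(0, nrow(pts), 3L)
    dp[, d] <- hstep
    fd <- -(sphere_potential(model, pts + dp) -
      sphere_potential(model, pts - dp)) / (2 * hstep)
    expect_lt(max(abs(fd - E[, d])) / max(abs(E)), 1e-6)
  }
})

test_that("field scales linearly with the injected current", {
  pts <- matrix(c(0.01, 0.02, 0.06, -0.03, 0.01, 0.05), ncol = 3L, byrow = TRUE)
  m1 <- default_sphere_model(current = 2e-3, L = 60L)
  m2 <- default_sphere_model(current = 4e-3, L = 60L)
  expect_equal(
    sphere_efield(m2, pts), 2 * sphere_efield(m1, pts),
    tolerance = 1e-12
  )
})

test_that("an insulating skull attenuates the cortical field", {
  caps <- list(
    list(direction = ten_ten_direction("F3"), area = 25e-4, current = 2e-3),
    list(direction = ten_ten_direction("F4"), area = 25e-4, current = -2e-3)
  )
  radii <- c(0.092, 0.086, 0.08, 0.078, 0.06)
  probe <- matrix(ten_ten_direction("F3") * 0.069, ncol = 3L) # GM-shell midpoint
  mag_with_skull_sigma <- function(s) {
    m <- sphere_model(radii, c(0.465, s, 1.654, 0.275, 0.126), caps, L = 100L)
    sqrt(sum(sphere_efield(m, probe)^2))
  }
  expect_lt(mag_with_skull_sigma(0.01), mag_with_skull_sigma(0.465))
})

test_that("model validation rejects unphysical inputs", {
  caps <- list(
    list(direction = c(0, 0, 1), area = 25e-4, current = 2e-3),
    list(direction = c(0, 0, -1), area = 25e-4, current = -2e-3)
  )
  expect_error(sphere_model(c(0.08, 0.09), c(1, 1), caps), "decreasing")
  expect_error(sphere_model(c(0.09, 0.08), c(1, -1), caps), "positive")
  expect_error(sphere_model(0.09, 1, caps, L = 5L), "at least 10")
  caps_bad <- caps
  caps_bad[[2L]]$current <- -1e-3
  expect_error(sphere_model(0.09, 1, caps_bad), "sum to zero")
})
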