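# Analytic forward solution for a multilayer concentric sphere with uniform
# spherical-cap current injection: per-degree Legendre series with a 2x2
# transfer recursion across isotropic layers. Serves as the independent
# correctness oracle for the finite-element solver.

#' Specify an analytic multilayer sphere model
#'
#' @param radii Layer outer radii in meters, strictly decreasing
#'   (outermost first); the last layer fills the core.
#' @param sigma Scalar conductivity per layer (S/m), same length.
#' @param caps List of electrode caps, each a list with `direction` (unit
#'   vector), `area` (m^2) or `half_angle` (rad), and `current` (A). Currents
#'   must sum to zero.
#' @param L Series truncation degree (`>= 10`).
#' @return Object of class `sphere_model`.
#' @export
sphere_model <- function(radii, sigma, caps, L = 100L) {
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (length(sigma) != length(radii)) stop("one conductivity per layer")
  if (any(sigma <= 0)) stop("conductivities must be positive")
  if (L < 10L) stop("truncation order L must be at least 10")
  caps <- lapply(caps, function(cp) {
    cp$direction <- cp$direction / sqrt(sum(cp$direction^2))
    if (is.null(cp$half_angle)) {
      cp$half_angle <- acos(1 - cp$area / (2 * pi * radii[1L]^2))
    }
    cp
  })
  tot <- sum(vapply(caps, function(cp) cp$current, numeric(1L)))
  if (abs(tot) > 1e-12 * max(abs(vapply(caps, function(cp) cp$current, numeric(1L))))) {
    stop("cap currents must sum to zero")
  }
  structure(
    list(radii = radii, sigma = sigma, caps = caps, L = as.integer(L)),
    class = "sphere_model"
  )
}

#' Default five-layer head sphere model
#'
#' The default layered phantom (scalp/skull/CSF/GM/WM radii 92/86/80/78/60 mm)
#' with the standard tissue conductivities and two 25 cm^2 caps at +/- 2 mA.
#'
#' @param anode,cathode Unit direction vectors of the two caps.
#' @param current Injected current (A).
#' @param area Cap area (m^2).
#' @inheritParams sphere_model
#' @export
default_sphere_model <- function(anode = ten_ten_direction("F3"),
                                 cathode = ten_ten_direction("F4"),
                                 current = 2e-3, area = 25e-4, L = 100L) {
  spec <- phantom_spec()
  sig <- conductivity_defaults()[spec$labels]
  sphere_model(
    radii = spec$radii, sigma = unname(sig),
    caps = list(
      list(direction = anode, area = area, current = current),
      list(direction = cathode, area = area, current = -current)
    ),
    L = L
  )
}

# Legendre polynomial values P_0..P_L at scalar x (vector over degrees).
legendre_upto <- function(L, x) {
  p <- numeric(L + 1L)
  p[1L] <- 1
  if (L >= 1L) p[2L] <- x
  for (l in 2:L) {
    p[l + 1L] <- ((2 * l - 1) * x * p[l] - (l - 1) * p[l - 1L]) / l
  }
  p
}

#' Legendre expansion coefficients of the cap current densities
#'
#' Expands each cap's uniform inward current density in Legendre polynomials
#' about its own axis: with `c = cos(half_angle)` and uniform density
#' `j0 = I / (2 pi R^2 (1 - c))`, the degree-`l` coefficient is
#' `g_l = j0 (P_(l-1)(c) - P_(l+1)(c)) / 2` for `l >= 1` (the cap integral
#' identity), and `g_0 = j0 (1 - c) / 2`. The degree-0 coefficients of a
#' balanced montage cancel.
#'
#' @param model A [sphere_model()].
#' @return A list per cap with `g` (numeric vector, degrees 0..L), `j0`, and
#'   the cap geometry.
#' @export
cap_source_coefficients <- function(model) {
  L <- model$L
  R <- model$radii[1L]
  lapply(model$caps, function(cp) {
    ca <- cos(cp$half_angle)
    j0 <- cp$current / (2 * pi * R^2 * (1 - ca))
    p <- legendre_upto(L + 1L, ca) # P_0 .. P_{L+1}
    g <- numeric(L + 1L)
    g[1L] <- j0 * (1 - ca) / 2
    for (l in 1:L) {
      g[l + 1L] <- j0 * (p[l] - p[l + 2L]) / 2
    }
    list(g = g, j0 = j0, direction = cp$direction, half_angle = cp$half_angle)
  })
}

# Per-degree layer coefficients (unscaled) by outward transfer recursion.
# Layer k potential: f(r) = A_k (r/R_k)^l + B_k (R_{k+1}/r)^{l+1}
# (innermost layer: B = 0, normalization A = 1). Returns A, B matrices
# (layers x degrees 1..L) plus the outer-surface radial-derivative factor
# dphi(R_1) = (l A_1 - (l+1) B_1 t_1^{l+1}) / R_1 per degree.
layer_coefficients <- function(model) {
  R <- model$radii
  sig <- model$sigma
  K <- length(R)
  L <- model$L
  A <- matrix(0, K, L)
  B <- matrix(0, K, L)
  dphi_out <- numeric(L)
  # t_k = R_{k+1}/R_k inside-to-outside ratio of layer k
  t <- c(R[-1L] / R[-K], 0)
  for (l in seq_len(L)) {
    A[K, l] <- 1
    B[K, l] <- 0
    phi <- 1 # value at r = R_K (outer boundary of core)
    flux <- sig[K] * l / R[K] # sigma dphi/dr at R_K
    if (K >= 2L) {
      for (k in (K - 1L):1L) {
        # interface at r = R_{k+1}: continuity of phi and sigma dphi/dr
        P <- t[k]^l
        G <- flux * R[k + 1L] / sig[k]
        A[k, l] <- ((l + 1) * phi + G) / ((2 * l + 1) * P)
        B[k, l] <- phi - A[k, l] * P
        # value and flux at the outer boundary of layer k (r = R_k)
        phi <- A[k, l] + B[k, l] * t[k]^(l + 1)
        flux <- sig[k] * (l * A[k, l] - (l + 1) * B[k, l] * t[k]^(l + 1)) / R[k]
      }
    }
    dphi_out[l] <- flux / sig[1L] # dphi/dr at R_1 for unit core scale
  }
  list(A = A, B = B, dphi_out = dphi_out, t = t)
}

# Map observation points to layers. Points exactly on an interface go to the
# outer layer (values are continuous there anyway).
assign_layer <- function(model, r) {
  K <- length(model$radii)
  layer <- rep(K, length(r))
  for (k in seq_len(K - 1L)) {
    layer[r <= model$radii[k] & r > model$radii[k + 1L]] <- k
  }
  layer[r > model$radii[1L]] <- NA_integer_
  layer
}

# Shared series evaluation. Returns phi and (optionally) E at points.
sphere_series_eval <- function(model, points, want_e = FALSE) {
  points <- as.matrix(points)
  r <- sqrt(rowSums(points^2))
  if (any(r > model$radii[1L] * (1 + 1e-12))) {
    stop("observation points must lie inside the outer sphere")
  }
  layer <- assign_layer(model, r)
  n <- nrow(points)
  K <- length(model$radii)
  L <- model$L
  lay <- layer_coefficients(model)
  src <- cap_source_coefficients(model)
  R1 <- model$radii[1L]
  Rk <- model$radii[layer]
  Rk1 <- c(model$radii[-1L], 0)[layer] # inner radius of the point's layer
  rr <- pmax(r, 1e-12)
  rhat <- points / rr
  up <- r / Rk # (r / R_k) per point
  dn <- Rk1 / rr # (R_{k+1} / r) per point

  phi <- numeric(n)
  E <- if (want_e) matrix(0, n, 3L) else NULL

  sigma1 <- model$sigma[1L]
  for (cap in src) {
    u <- pmin(1, pmax(-1, (rhat %*% cap$direction)[, 1L]))
    p_prev <- rep(1, n) # P_0
    p_cur <- u # P_1
    dp_prev <- rep(0, n) # P_0'
    dp_cur <- rep(1, n) # P_1'
    upl <- up # up^l, starts at l = 1
    dnl <- dn^2 # dn^(l+1), starts at l = 1
    for (l in seq_len(L)) {
      # scale so that sigma_1 dphi/dr (R_1) = g_l
      cscale <- cap$g[l + 1L] / (sigma1 * lay$dphi_out[l])
      Av <- lay$A[cbind(layer, l)] * cscale
      Bv <- lay$B[cbind(layer, l)] * cscale
      f <- Av * upl + Bv * dnl
      phi <- phi + f * p_cur
      if (want_e) {
        fp <- (l * Av * upl - (l + 1) * Bv * dnl) / rr
        # grad phi = f'(r) P_l(u) rhat + f(r)/r P_l'(u) (d - u rhat)
        gcoef <- f / rr * dp_cur
        E[, 1L] <- E[, 1L] - (fp * p_cur - gcoef * u) * rhat[, 1L] -
          gcoef * cap$direction[1L]
        E[, 2L] <- E[, 2L] - (fp * p_cur - gcoef * u) * rhat[, 2L] -
          gcoef * cap$direction[2L]
        E[, 3L] <- E[, 3L] - (fp * p_cur - gcoef * u) * rhat[, 3L] -
          gcoef * cap$direction[3L]
      }
      if (l < L) {
        # advance recurrences to degree l + 1
        p_next <- ((2 * l + 1) * u * p_cur - l * p_prev) / (l + 1)
        dp_next <- u * dp_cur + (l + 1) * p_cur # P'_{l+1} = u P'_l + (l+1) P_l
        p_prev <- p_cur
        p_cur <- p_next
        dp_prev <- dp_cur
        dp_cur <- dp_next
        upl <- upl * up
        dnl <- dnl * dn
      }
    }
  }
  # multiply by 1/R1? No: cscale carries full dimensions (dphi_out has 1/m).
  list(phi = phi, E = E, layer = layer)
}

#' Analytic potential of the multilayer sphere model
#'
#' Evaluates the Legendre-series potential at interior observation points.
#' The potential is gauge-free mean-zero over any full sphere (no degree-0
#' term survives a balanced montage).
#'
#' @param model A [sphere_model()].
#' @param points n x 3 matrix of observation points (m), inside the outer
#'   sphere.
#' @return Numeric vector of potentials (V).
#' @export
sphere_potential <- function(model, points) {
  sphere_series_eval(model, points, want_e = FALSE)$phi
}

#' Analytic electric field of the multilayer sphere model
#'
#' Term-wise gradient of the series: `E = -grad(phi)`.
#'
#' @inheritParams sphere_potential
#' @return n x 3 matrix of E-field vectors (V/m).
#' @export
sphere_efield <- function(model, points) {
  sphere_series_eval(model, points, want_e = TRUE)$E
}

#' Reconstructed surface current density of the cap expansion
#'
#' Evaluates the truncated Legendre expansion of the injected current density
#' at surface angles, for convergence checks against the exact cap indicator.
#'
#' @param model A [sphere_model()].
#' @param cos_gamma Cosine of the polar angle from a cap's axis.
#' @param cap_index Which cap.
#' @return Reconstructed inward current density (A/m^2) at those angles.
#' @export
reconstruct_cap_density <- function(model, cos_gamma, cap_index = 1L) {
  src <- cap_source_coefficients(model)[[cap_index]]
  vapply(cos_gamma, function(u) {
    p <- legendre_upto(model$L, u)
    sum(src$g * p)
  }, numeric(1L))
}

#' Interface continuity residuals of the analytic solution
#'
#' Self-check: per-degree relative mismatch of potential and normal current
#' density across each internal interface (analytically zero; numerically
#' bounded by round-off of the transfer recursion).
#'
#' @param model A [sphere_model()].
#' @return Maximum relative residual over interfaces and degrees.
#' @export
oracle_continuity_residual <- function(model) {
  lay <- layer_coefficients(model)
  R <- model$radii
  sig <- model$sigma
  K <- length(R)
  if (K < 2L) return(0)
  worst <- 0
  for (l in seq_len(model$L)) {
    for (k in seq_len(K - 1L)) {
      tk <- lay$t[k]
      # outer-layer side at r = R_{k+1}
      phi_o <- lay$A[k, l] * tk^l + lay$B[k, l]
      flx_o <- sig[k] * (l * lay$A[k, l] * tk^l - (l + 1) * lay$B[k, l]) / R[k + 1L]
      # inner-layer side
      tk1 <- if (k + 1L < K) lay$t[k + 1L] else 0
      phi_i <- lay$A[k + 1L, l] + lay$B[k + 1L, l] * tk1^(l + 1)
      flx_i <- sig[k + 1L] *
        (l * lay$A[k + 1L, l] - (l + 1) * lay$B[k + 1L, l] * tk1^(l + 1)) / R[k + 1L]
      rp <- abs(phi_o - phi_i) / max(abs(phi_o), abs(phi_i), 1e-300)
      rf <- abs(flx_o - flx_i) / max(abs(flx_o), abs(flx_i), 1e-300)
      worst <- max(worst, rp, rf)
    }
  }
  worst
}
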