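# P1 tetrahedral finite-element solver for the quasi-static conduction
# problem div(sigma grad(phi)) = 0 with Neumann current injection.

# Barycentric shape-function gradients per element. Returns list of three
# m x 4 matrices (gx, gy, gz): gradient component of shape function i on
# element e, plus the absolute element volumes.
shape_gradients <- function(mesh) {
  nd <- mesh$nodes
  el <- mesh$elements
  p <- lapply(1:4, function(i) nd[el[, i], , drop = FALSE])
  m <- nrow(el)
  gx <- gy <- gz <- matrix(0, m, 4L)
  # vertex i's gradient: normal of the opposite face, normalized so that
  # grad(lambda_i) . (p_i - p_j) = 1 for j on the face
  opp <- list(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
  for (i in 1:4) {
    o <- opp[[i]]
    b <- p[[o[1L]]]
    u <- p[[o[2L]]] - b
    v <- p[[o[3L]]] - b
    cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
    cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
    cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
    w <- p[[i]] - b
    dp <- w[, 1L] * cx + w[, 2L] * cy + w[, 3L] * cz
    gx[, i] <- cx / dp
    gy[, i] <- cy / dp
    gz[, i] <- cz / dp
  }
  list(gx = gx, gy = gy, gz = gz, volume = abs(tet_signed_volume(nd, el)))
}

#' Assemble the finite-element system for a montage
#'
#' Builds the P1 stiffness matrix `K[i,j] = sum_e V_e grad(l_i)' sigma_e
#' grad(l_j)` over all tetrahedra (scalar or tensor conductivity) and the
#' Neumann load vector from the montage's boundary current densities: an
#' electrode facet of area `A` carrying inward normal current density `j`
#' contributes `j A / 3` to each of its three nodes.
#'
#' @param mesh A [head_mesh()].
#' @param montage Optional [build_montage()] result supplying boundary data;
#'   `NULL` assembles the stiffness with a zero load.
#' @return Object of class `fem_system`: sparse symmetric `K` (dgCMatrix),
#'   load `b` (A), and the mesh dimensions.
#' @export
assemble_system <- function(mesh, montage = NULL) {
  stopifnot(inherits(mesh, "head_mesh"))
  g <- shape_gradients(mesh)
  el <- mesh$elements
  m <- nrow(el)
  nn <- nrow(mesh$nodes)
  tensor <- is.matrix(mesh$conductivity)

  if (tensor) {
    s <- mesh$conductivity # columns xx,yy,zz,xy,xz,yz
    sgx <- function(i) {
      s[, 1L] * g$gx[, i] + s[, 4L] * g$gy[, i] + s[, 5L] * g$gz[, i]
    }
    sgy <- function(i) {
      s[, 4L] * g$gx[, i] + s[, 2L] * g$gy[, i] + s[, 6L] * g$gz[, i]
    }
    sgz <- function(i) {
      s[, 5L] * g$gx[, i] + s[, 6L] * g$gy[, i] + s[, 3L] * g$gz[, i]
    }
  }

  ii <- jj <- integer(16L * m)
  xx <- numeric(16L * m)
  k <- 0L
  for (i in 1:4) {
    if (tensor) {
      sx <- sgx(i); sy <- sgy(i); sz <- sgz(i)
    }
    for (j in 1:4) {
      val <- if (tensor) {
        g$volume * (sx * g$gx[, j] + sy * g$gy[, j] + sz * g$gz[, j])
      } else {
        g$volume * mesh$conductivity *
          (g$gx[, i] * g$gx[, j] + g$gy[, i] * g$gy[, j] + g$gz[, i] * g$gz[, j])
      }
      idx <- k * m + seq_len(m)
      ii[idx] <- el[, i]
      jj[idx] <- el[, j]
      xx[idx] <- val
      k <- k + 1L
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))

  b <- numeric(nn)
  if (!is.null(montage)) {
    bd <- montage$boundary
    contrib <- bd$density * bd$area / 3
    for (c_ in 1:3) {
      b <- b + tabulate_double(bd$tri[, c_], contrib, nn)
    }
  }
  structure(
    list(K = K, b = b, n_nodes = nn, n_elements = m),
    class = "fem_system"
  )
}

# Sum `vals` into bins `idx` over 1..n (double-precision tabulate).
tabulate_double <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Solve for node potentials
#'
#' Solves the assembled system under the mean-zero gauge: one node is pinned
#' during the sparse Cholesky factorization (the matrix has the constants in
#' its null space), and the solution is recentred to mean zero afterwards.
#' The contract is on the relative residual, not the solver.
#'
#' @param system An [assemble_system()] result.
#' @param rel_tol Maximum admissible relative residual `|K phi - b| / |b|`.
#' @param factor Optional pre-computed Cholesky factorization of the reduced
#'   matrix (from [fem_factorize()]), reused across right-hand sides.
#' @return List: `phi` (node potentials, V, mean zero), `residual` (relative),
#'   `pinned` (index of the pinned node).
#' @export
solve_potential <- function(system, rel_tol = 1e-10, factor = NULL) {
  b <- system$b
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    return(list(phi = numeric(system$n_nodes), residual = 0, pinned = 1L))
  }
  if (abs(sum(b)) > 1e-12 * sum(abs(b))) {
    stop("right-hand side is not balanced: net injected current must be zero")
  }
  if (is.null(factor)) factor <- fem_factorize(system)
  pin <- factor$pinned
  phi1 <- Matrix::solve(factor$chol, b[-pin])
  phi <- numeric(system$n_nodes)
  phi[-pin] <- as.numeric(phi1)
  phi <- phi - mean(phi)
  res <- sqrt(sum((as.numeric(system$K %*% phi) - b)^2)) / nb
  if (res > rel_tol) {
    stop(sprintf(
      "solver residual %.3e exceeds rel_tol %.1e", res, rel_tol
    ))
  }
  list(phi = phi, residual = res, pinned = pin)
}

#' Factorize the reduced stiffness matrix
#'
#' Sparse Cholesky factorization of the stiffness matrix with one pinned
#' node removed (gauge fixing). Reuse across montages sharing a mesh.
#'
#' @param system An [assemble_system()] result.
#' @param pin Node index to pin (default 1).
#' @return List with `chol` (a `CHMfactor`) and `pinned`.
#' @export
fem_factorize <- function(system, pin = 1L) {
  K11 <- system$K[-pin, -pin]
  list(
    chol = Matrix::Cholesky(Matrix::forceSymmetric(K11),
      LDL = FALSE, super = TRUE
    ),
    pinned = pin
  )
}

#' Compute the element-wise electric field from node potentials
#'
#' `E = -grad(phi)`, constant per P1 element; the magnitude is the Euclidean
#' vector norm.
#'
#' @param mesh A [head_mesh()].
#' @param phi Node potentials (V).
#' @param diagnostics Optional solver diagnostics carried through.
#' @return Object of class `field_solution`: `phi`, `E` (m x 3, V/m),
#'   `magnitude` (V/m), `diagnostics`.
#' @export
compute_efield <- function(mesh, phi, diagnostics = NULL) {
  g <- shape_gradients(mesh)
  el <- mesh$elements
  ex <- ey <- ez <- numeric(nrow(el))
  for (i in 1:4) {
    pv <- phi[el[, i]]
    ex <- ex - pv * g$gx[, i]
    ey <- ey - pv * g$gy[, i]
    ez <- ez - pv * g$gz[, i]
  }
  E <- cbind(ex, ey, ez)
  structure(
    list(
      phi = phi, E = E, magnitude = sqrt(rowSums(E^2)),
      diagnostics = diagnostics
    ),
    class = "field_solution"
  )
}

#' Solve one montage on one mesh
#'
#' Convenience wrapper: assemble, factorize (or reuse), solve, differentiate.
#'
#' @inheritParams assemble_system
#' @inheritParams solve_potential
#' @param stiffness Optional pre-assembled `fem_system` (stiffness only) and
#' @param factor optional factorization, both reused across montages.
#' @return A `field_solution`.
#' @export
solve_montage <- function(mesh, montage, rel_tol = 1e-10,
                          stiffness = NULL, factor = NULL) {
  if (is.null(stiffness)) stiffness <- assemble_system(mesh, montage)
  sys <- stiffness
  if (is.null(montage)) stop("montage required")
  if (all(sys$b == 0)) {
    bd <- montage$boundary
    contrib <- bd$density * bd$area / 3
    b <- numeric(sys$n_nodes)
    for (c_ in 1:3) b <- b + tabulate_double(bd$tri[, c_], contrib, sys$n_nodes)
    sys$b <- b
  }
  sol <- solve_potential(sys, rel_tol = rel_tol, factor = factor)
  compute_efield(mesh, sol$phi, diagnostics = list(residual = sol$residual))
}

#' Attach synthetic anisotropic white-matter conductivity tensors
#'
#' Replaces the scalar WM conductivity by an axially symmetric tensor whose
#' principal axes are tangential to the sphere (default convention) with
#' anisotropy ratio `rho = sigma_t / sigma_r >= 1`, scaled so the geometric
#' mean of the eigenvalues equals the scalar WM value (volume-normalized
#' mapping): `sigma_t = sigma rho^(1/3)`, `sigma_r = sigma rho^(-2/3)`.
#'
#' @param mesh A [head_mesh()] with scalar conductivities.
#' @param rho Anisotropy ratio, `>= 1`. `rho = 1` reproduces the isotropic
#'   mesh exactly (tensors equal `sigma * I`).
#' @return The mesh with an m x 6 tensor conductivity matrix.
#' @export
tensorize_wm <- function(mesh, rho = 1) {
  stopifnot(inherits(mesh, "head_mesh"))
  if (rho < 1) stop("anisotropy ratio rho must be >= 1")
  if (is.matrix(mesh$conductivity)) stop("mesh already carries tensors")
  sig <- mesh$conductivity
  m <- length(sig)
  tens <- cbind(sig, sig, sig, 0, 0, 0)
  colnames(tens) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  wm <- which(mesh$tissue == "WM")
  if (length(wm) > 0L) {
    cen <- tet_centroids(mesh)[wm, , drop = FALSE]
    r <- sqrt(rowSums(cen^2))
    r[r == 0] <- 1
    n <- cen / r
    s <- sig[wm]
    st <- s * rho^(1 / 3)
    sr <- s * rho^(-2 / 3)
    d <- sr - st # tensor = st * I + d * n n'
    tens[wm, 1L] <- st + d * n[, 1L]^2
    tens[wm, 2L] <- st + d * n[, 2L]^2
    tens[wm, 3L] <- st + d * n[, 3L]^2
    tens[wm, 4L] <- d * n[, 1L] * n[, 2L]
    tens[wm, 5L] <- d * n[, 1L] * n[, 3L]
    tens[wm, 6L] <- d * n[, 2L] * n[, 3L]
  }
  mesh$conductivity <- tens
  mesh
}

#' Net radial current through a spherical surface inside the mesh
#'
#' Sums the outward normal component of the current density `J = sigma E`
#' over the mesh facets lying on the sphere of radius `r` (a tissue
#' interface of a layered-sphere mesh), using the element on the inner side
#' of each facet. Used as a conservation diagnostic: between the electrodes,
#' the hemispherical flux should equal the injected current.
#'
#' @param mesh A [head_mesh()] built by [build_layered_sphere()].
#' @param field A [compute_efield()] result.
#' @param r Sphere radius (m) at a node shell.
#' @param axis Unit vector; only facets with centroid on the positive-`axis`
#'   hemisphere are summed (a closed interface sphere has zero net flux).
#'   `NULL` sums the full sphere.
#' @return Net current in A through the (hemi)sphere, oriented along `axis`.
#' @export
interface_current <- function(mesh, field, r, axis = NULL) {
  nd <- mesh$nodes
  rn <- sqrt(rowSums(nd^2))
  on_sphere <- abs(rn - r) < 1e-9 + 1e-6 * r
  el <- mesh$elements
  faces <- rbind(
    el[, c(2L, 3L, 4L)], el[, c(1L, 4L, 3L)],
    el[, c(1L, 2L, 4L)], el[, c(1L, 3L, 2L)]
  )
  owner <- rep(seq_len(nrow(el)), times = 4L)
  on_face <- on_sphere[faces[, 1L]] & on_sphere[faces[, 2L]] & on_sphere[faces[, 3L]]
  faces <- faces[on_face, , drop = FALSE]
  owner <- owner[on_face]
  if (nrow(faces) == 0L) stop("no mesh facets on the sphere of radius r")
  # keep inner-side owners only (centroid radius below r)
  cen_r <- sqrt(rowSums(tet_centroids(mesh)^2))
  inner <- cen_r[owner] < r
  faces <- faces[inner, , drop = FALSE]
  owner <- owner[inner]
  geom <- triangle_geometry(nd, faces)
  # orient normals outward (radially)
  sgn <- sign(rowSums(geom$normal * geom$centroid))
  normal <- geom$normal * sgn
  sig <- mesh$conductivity
  E <- field$E[owner, , drop = FALSE]
  if (is.matrix(sig)) {
    s <- sig[owner, , drop = FALSE]
    J <- cbind(
      s[, 1L] * E[, 1L] + s[, 4L] * E[, 2L] + s[, 5L] * E[, 3L],
      s[, 4L] * E[, 1L] + s[, 2L] * E[, 2L] + s[, 6L] * E[, 3L],
      s[, 5L] * E[, 1L] + s[, 6L] * E[, 2L] + s[, 3L] * E[, 3L]
    )
  } else {
    J <- E * sig[owner]
  }
  flux <- rowSums(J * normal) * geom$area
  if (!is.null(axis)) {
    keep <- (geom$centroid %*% axis)[, 1L] > 0
    flux <- flux[keep]
  }
  sum(flux)
}
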