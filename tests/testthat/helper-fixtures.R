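# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# single regular tetrahedron with edge `a`, labelled GM
regular_tet_mesh <- function(a = 1, tissue = "GM") {
  nodes <- rbind(
    c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
    c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3))
  )
  head_mesh(nodes, rbind(1:4), tissue)
}

# unit cube split into 6 Kuhn tetrahedra
cube_mesh <- function(tissue = "GM") {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # Kuhn triangulation: path simplices through the main diagonal
  perms <- rbind(
    c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
    c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8)
  )
  head_mesh(v, perms, rep(tissue, nrow(perms)))
}

smoke_mesh <- function() {
  fixture("smoke_mesh", function() {
    build_layered_sphere(phantom_spec(), subdiv = 3L, h = 4e-3, wm_coarsen = 3)
  })
}

default_mesh <- function() {
  fixture("default_mesh", function() {
    build_layered_sphere(phantom_spec(), subdiv = 3L, h = 2e-3, wm_coarsen = 3)
  })
}

smoke_field <- function() {
  fixture("smoke_field", function() {
    mesh <- smoke_mesh()
    mon <- build_montage(mesh, "F3-F4")
    list(mesh = mesh, montage = mon, field = solve_montage(mesh, mon))
  })
}

# independent sort-and-scan oracle for the volume-weighted percentile
brute_weighted_percentile <- function(values, weights, q) {
  o <- order(values)
  v <- values[o]
  w <- weights[o]
  total <- sum(w)
  acc <- 0
  for (i in seq_along(v)) {
    acc <- acc + w[i]
    if (acc / total >= q / 100 - 1e-12) {
      return(v[i])
    }
  }
  v[length(v)]
}

# closed-form spherical-shell volumes (cm^3) for a phantom spec
shell_volumes_cm3 <- function(spec) {
  r_out <- spec$radii
  r_in <- c(spec$radii[-1L], 0)
  stats::setNames(4 / 3 * pi * (r_out^3 - r_in^3) * 1e6, spec$labels)
}
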