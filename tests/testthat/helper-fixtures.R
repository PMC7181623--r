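# Shared fixtures: all meshes and records are built in code at test time.

# small implant-in-bone block (1,728 tets) for fast end-to-end runs
tiny_geometry <- function(grid_spacing = 0.001, implant_radius = 0.0015,
                          implant_length = 0.004, ...) {
  geometry_params(block_dims = c(0.006, 0.006, 0.008),
                  grid_spacing = grid_spacing,
                  implant_radius = implant_radius,
                  implant_length = implant_length, ...)
}

# assemble a bare oi_mesh from explicit arrays (for solver unit tests)
manual_mesh <- function(coords, tets, region, fixed = integer(),
                        top = integer()) {
  storage.mode(tets) <- "integer"
  centroids <- (coords[tets[, 1], , drop = FALSE] +
                coords[tets[, 2], , drop = FALSE] +
                coords[tets[, 3], , drop = FALSE] +
                coords[tets[, 4], , drop = FALSE]) / 4
  if (nrow(tets) == 1) centroids <- matrix(centroids, 1, 3)
  structure(list(coords = coords, tets = tets, region = region,
                 centroids = centroids,
                 node_sets = list(FIXED = fixed, IMPLANT_TOP = top),
                 element_sets = list(IMPLANT = which(region == "IMPLANT"),
                                     CORTICAL = which(region == "CORTICAL"),
                                     CANCELLOUS = which(region == "CANCELLOUS"),
                                     INTERFACE = integer()),
                 modulus_scale = rep(1, nrow(tets)),
                 params = NULL), class = "oi_mesh")
}

# one reference tetrahedron with unit legs scaled by `a`
single_tet_mesh <- function(a = 0.001, region = "IMPLANT") {
  coords <- rbind(c(0, 0, 0), c(a, 0, 0), c(0, a, 0), c(0, 0, a))
  manual_mesh(coords, matrix(c(1L, 2L, 3L, 4L), 1, 4), region)
}

# uniform material library: same elastic constants everywhere, bone yields
# optionally overridden
uniform_materials <- function(E = 1e9, nu = 0, rho = 1000,
                              cortical_yield = 1e30, cancellous_yield = 1e30) {
  m <- elastic_material(E, nu, rho)
  material_library(cortical = m, cancellous = m, implant = m,
                   cortical_yield = cortical_yield,
                   cancellous_yield = cancellous_yield)
}

# long thin uniform bar for 1-D wave propagation checks (nu = 0)
bar_fixture <- function(L = 0.04, w = 0.001, h = 2.5e-4, E = 1e9, rho = 1000) {
  gp <- geometry_params(block_dims = c(w, w, L), grid_spacing = h,
                        implant_radius = h, implant_length = 2 * h,
                        cortical_thickness = h)
  mesh <- build_mesh(gp)
  mesh$region[] <- "IMPLANT"   # uniform, no failure anywhere
  mesh$element_sets$IMPLANT <- seq_along(mesh$region)
  mesh$element_sets$CORTICAL <- integer()
  mesh$element_sets$CANCELLOUS <- integer()
  model <- fe_model(mesh, uniform_materials(E = E, nu = 0, rho = rho),
                    fixed_nodes = integer(), allow_free = TRUE)
  list(mesh = mesh, model = model, L = L, w = w, h = h, c0 = sqrt(E / rho))
}

# launch a resolved (smooth, ~12-layer) compression pulse down the bar and
# measure its front speed between two stations plus the energy-ledger drift.
# A single-layer impulse would put all content at the grid frequency, where
# the lattice is dispersive; a resolved pulse travels at the continuum speed.
measure_bar_wave <- function(fx = bar_fixture(), pulse_width = 0.003,
                             threshold = 0.5) {
  st <- sim_state(fx$model)
  z <- fx$mesh$coords[, 3]
  st$vel[, 3] <- ifelse(z < pulse_width, cos(pi * z / (2 * pulse_width))^2, 0)
  hist <- fem_run(fx$model,
                  time_integration_params(t_end = 0.85 * fx$L / fx$c0,
                                          output_every = 1L), state = st)
  sn <- hist$snapshots
  ctr <- fx$mesh$centroids
  on_axis <- abs(ctr[, 1] - fx$w / 2) < fx$h * 1.2 &
    abs(ctr[, 2] - fx$w / 2) < fx$h * 1.2
  station <- function(zz) which(on_axis)[which.min(abs(ctr[on_axis, 3] - zz))]
  arrival <- function(elem) {
    v <- sn$vm[elem, ]
    thr <- threshold * max(v)
    i <- which(v > thr)[1]
    t <- as.numeric(sn$time)
    t[i - 1] + (t[i] - t[i - 1]) * (thr - v[i - 1]) / (v[i] - v[i - 1])
  }
  speed <- (0.4 * fx$L) /
    (arrival(station(0.7 * fx$L)) - arrival(station(0.3 * fx$L)))
  # interior ledger rows only: the terminal snapshot's kinetic entry uses
  # instantaneous velocities, not the staggered leapfrog product
  en <- hist$energy
  interior <- en$total_J[2:(nrow(en) - 1)]
  list(speed = speed, history = hist,
       drift = max(abs(interior - interior[1])),
       peak_kinetic = max(en$kinetic_J))
}

# default SHPB rig: the steel pressure bars
steel_bar <- function() bar_properties(E = 209e9, rho = 7830)

cortical_specimen <- function() specimen_geometry(length = 0.008,
                                                  area = 0.006 * 0.003)
cancellous_specimen <- function() specimen_geometry(length = 0.005,
                                                    area = 0.006 * 0.006)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * abs(expected))
}
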