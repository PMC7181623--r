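# Solver verification: closed-form single-element oracles, numerical
# gradient/energy oracles, patch test, 1-D wave-speed oracle, conservation.

test_that("lumped mass splits rho V equally and conserves total mass", {
  mesh <- single_tet_mesh(a = 0.002884499)   # V ~ 4e-9 m^3
  model <- fe_model(mesh, uniform_materials(rho = 1000),
                    fixed_nodes = integer(), allow_free = TRUE)
  m <- lumped_mass(model)
  V <- tet_volumes(mesh)
  expect_equal(m, rep(1000 * V / 4, 4), tolerance = 1e-12)
  expect_equal(m[1], 1e-6, tolerance = 1e-3)
  # uniform-density block: total nodal mass = rho * block volume
  bm <- build_mesh(tiny_geometry())
  bmodel <- fe_model(bm, uniform_materials(rho = 1234))
  expect_rel_equal(sum(lumped_mass(bmodel)),
                   1234 * prod(bm$params$block_dims), 1e-12)
  # node shared by k tets accumulates each element's quarter share
  shared <- as.integer(names(which.max(table(bm$tets))))
  adj <- which(apply(matrix(bm$tets == shared, ncol = 4), 1, any))
  expect_rel_equal(lumped_mass(bmodel)[shared],
                   sum(1234 * tet_volumes(bm)[adj] / 4), 1e-12)
})

test_that("element stress: uniaxial stretch closed form and rigid-motion invariance", {
  mesh <- single_tet_mesh(a = 0.001)
  E <- 2e9
  model <- fe_model(mesh, uniform_materials(E = E, nu = 0),
                    fixed_nodes = integer(), allow_free = TRUE)
  alpha <- 1e-4
  disp <- cbind(0, 0, alpha * mesh$coords[, 3])
  s <- element_stress(model, 1, disp)
  expect_rel_equal(s[3, 3], E * alpha, 1e-12)
  expect_lt(max(abs(s[-9])), 1e-12 * E * alpha)
  # rigid translation and zero displacement produce zero stress
  expect_equal(element_stress(model, 1, matrix(1e-3, 4, 3)), matrix(0, 3, 3))
  expect_equal(element_stress(model, 1, matrix(0, 4, 3)), matrix(0, 3, 3))
})

test_that("element strain matches an independent linear-field gradient oracle", {
  set.seed(11)
  mesh <- single_tet_mesh(a = 0.001)
  model <- fe_model(mesh, uniform_materials(E = 1e9, nu = 0.25),
                    fixed_nodes = integer(), allow_free = TRUE)
  disp <- matrix(rnorm(12, sd = 1e-6), 4, 3)
  # oracle: solve the exact linear interpolant u = c0 + G x on the vertices
  X <- cbind(1, mesh$coords)
  G <- t(solve(X, disp))[, 2:4]    # 3x3 displacement gradient
  eps <- 0.5 * (G + t(G))
  lm_ <- lame_parameters(elastic_material(1e9, 0.25, 1000))
  sig_oracle <- lm_[["lambda"]] * sum(diag(eps)) * diag(3) +
    2 * lm_[["mu"]] * eps
  s <- element_stress(model, 1, disp)
  expect_lt(max(abs(s - sig_oracle)), 1e-8 * max(abs(sig_oracle)))
})

test_that("internal forces balance and equal minus the strain-energy gradient", {
  set.seed(7)
  mesh <- build_mesh(tiny_geometry())
  model <- fe_model(mesh, uniform_materials(E = 1e9, nu = 0.3))
  expect_equal(internal_forces(model, matrix(0, nrow(mesh$coords), 3)),
               matrix(0, nrow(mesh$coords), 3))
  # single stretched tet: internal nodal forces sum to the zero vector
  tet <- single_tet_mesh()
  tmodel <- fe_model(tet, uniform_materials(E = 1e9, nu = 0.2),
                     fixed_nodes = integer(), allow_free = TRUE)
  f1 <- internal_forces(tmodel, cbind(0, 0, 1e-4 * tet$coords[, 3]))
  expect_lt(max(abs(colSums(f1))), 1e-9 * max(abs(f1)))
  # energy gradient oracle on the block mesh
  disp <- matrix(rnorm(3 * nrow(mesh$coords), sd = 1e-7),
                 nrow(mesh$coords), 3)
  total_energy <- function(u) {
    s <- element_stresses(model, u)
    lam <- model$lambda; mu <- model$mu
    tr_eps <- (s[, 1] + s[, 2] + s[, 3]) / (3 * lam + 2 * mu)
    e <- s
    e[, 1:3] <- (s[, 1:3] - lam * tr_eps) / (2 * mu)
    e[, 4:6] <- s[, 4:6] / (2 * mu)
    sum(model$vol * 0.5 * (rowSums(s[, 1:3] * e[, 1:3]) +
                           2 * rowSums(s[, 4:6] * e[, 4:6])))
  }
  f <- internal_forces(model, disp)
  delta <- 1e-9
  for (k in c(1L, 200L, 440L)) {
    for (j in 1:3) {
      up <- disp; up[k, j] <- up[k, j] + delta
      dn <- disp; dn[k, j] <- dn[k, j] - delta
      grad <- (total_energy(up) - total_energy(dn)) / (2 * delta)
      expect_rel_equal(-grad, f[k, j], 1e-5)
    }
  }
})

test_that("stable time step: regular-tet closed form, cfl linearity, deletion monotonicity", {
  a <- 0.001
  coords <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
                  c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  mesh <- manual_mesh(coords, matrix(1:4, 1, 4), "IMPLANT")
  rho <- 1000; E <- 5000^2 * rho   # c_d = 5000 m/s at nu = 0
  model <- fe_model(mesh, uniform_materials(E = E, nu = 0, rho = rho),
                    fixed_nodes = integer(), allow_free = TRUE)
  h_alt <- a * sqrt(2 / 3)   # altitude of a regular tetrahedron
  expect_rel_equal(stable_dt(model, cfl_factor = 0.5), 0.5 * h_alt / 5000, 1e-9)
  expect_rel_equal(stable_dt(model, cfl_factor = 1),
                   2 * stable_dt(model, cfl_factor = 0.5), 1e-12)
  # deleting elements cannot decrease the stable step
  bm <- build_mesh(tiny_geometry())
  bmodel <- fe_model(bm, uniform_materials())
  act <- rep(TRUE, nrow(bm$tets))
  dt_all <- stable_dt(bmodel, act)
  act[which.min(bmodel$altitudes)] <- FALSE
  expect_gte(stable_dt(bmodel, act), dt_all)
  expect_error(stable_dt(bmodel, rep(FALSE, nrow(bm$tets))), "no active")
})

test_that("penalty contact: gap cases, south-pole direction, action-reaction", {
  mesh <- build_mesh(tiny_geometry())
  imp <- impactor(radius = 0.005, mass = 0.01, velocity = c(0, 0, -1),
                  center = c(0.003, 0.003, 0.02), penalty_stiffness = 1e6)
  model <- fe_model(mesh, uniform_materials(), imp = imp)
  st <- sim_state(model)
  # gap >= 0 everywhere: zero forces
  cf <- contact_force(model, st)
  expect_false(cf$any_contact)
  expect_equal(max(abs(cf$forces)), 0)
  # south pole penetration of depth d: force k d along the outward normal (-z)
  d <- 1e-5
  top_z <- max(mesh$coords[, 3])
  node <- mesh$node_sets$IMPLANT_TOP[
    which.min(rowSums((mesh$coords[mesh$node_sets$IMPLANT_TOP, ] -
                       matrix(c(0.003, 0.003, top_z),
                              length(mesh$node_sets$IMPLANT_TOP), 3,
                              byrow = TRUE))^2))]
  st$impactor_center <- c(mesh$coords[node, 1], mesh$coords[node, 2],
                          top_z + imp$radius - d)
  cf <- contact_force(model, st)
  expect_true(cf$any_contact)
  expect_equal(cf$forces[node, ], c(0, 0, -1e6 * d), tolerance = 1e-9)
  # action-reaction: nodal resultant + impactor reaction = 0
  expect_equal(colSums(cf$forces) + cf$reaction, c(0, 0, 0),
               tolerance = 1e-12 * 1e6 * d)
})

test_that("a step from rest with no impactor stays at rest; free body translates rigidly", {
  mesh <- build_mesh(tiny_geometry())
  model <- fe_model(mesh, uniform_materials())
  st <- sim_state(model)
  st2 <- fem_step(model, st, 1e-8)
  expect_equal(max(abs(st2$disp)), 0)
  expect_equal(max(abs(st2$stress)), 0)
  # free single element with uniform initial velocity: rigid translation
  tet <- single_tet_mesh()
  tmodel <- fe_model(tet, uniform_materials(),
                     fixed_nodes = integer(), allow_free = TRUE)
  st <- sim_state(tmodel)
  st$vel <- matrix(rep(c(1, -2, 0.5), each = 4), 4, 3)
  dt <- stable_dt(tmodel)
  for (i in 1:20) st <- fem_step(tmodel, st, dt)
  expect_lt(max(abs(st$stress)), 1e-6)
  expect_equal(st$disp, st$vel * st$time, tolerance = 1e-10)
})

test_that("compiled run and repeated single steps agree", {
  set.seed(3)
  mesh <- build_mesh(tiny_geometry())
  model <- fe_model(mesh, uniform_materials())
  st <- sim_state(model)
  st$vel <- matrix(rnorm(length(st$vel), sd = 0.01), nrow(st$vel), 3)
  st$vel[model$fixed_nodes, ] <- 0
  dt <- stable_dt(model)
  n <- 25L
  hist <- fem_run(model, time_integration_params(t_end = (n - 0.5) * dt,
                                                 output_every = 1L),
                  state = st, dt = dt)
  st_r <- st
  for (i in seq_len(n)) st_r <- fem_step(model, st_r, dt)
  expect_equal(hist$final$disp, st_r$disp, tolerance = 1e-13)
  expect_equal(hist$final$vel, st_r$vel, tolerance = 1e-13)
  expect_equal(hist$final$stress, st_r$stress, tolerance = 1e-13)
})

test_that("patch test: affine displacement gives the exact constant stress everywhere", {
  mesh <- build_mesh(tiny_geometry())
  model <- fe_model(mesh, uniform_materials(E = 3e9, nu = 0.3))
  A <- matrix(c(2, 1, 0, 1, -1, 3, 0, 3, 1), 3, 3) * 1e-4
  disp <- mesh$coords %*% t(A)
  s <- element_stresses(model, disp)
  eps <- 0.5 * (A + t(A))
  lm_ <- lame_parameters(elastic_material(3e9, 0.3, 1000))
  exact <- c(lm_[["lambda"]] * sum(diag(eps)) + 2 * lm_[["mu"]] * diag(eps),
             2 * lm_[["mu"]] * c(eps[1, 2], eps[2, 3], eps[3, 1]))
  for (j in 1:6)
    expect_lt(max(abs(s[, j] - exact[j])), 1e-8 * max(abs(exact)))
  # interior equilibrium: internal forces vanish away from the boundary
  f <- cpp_internal_forces(model$grads, model$vol, mesh$tets - 1L, s,
                           rep(1L, nrow(mesh$tets)), nrow(mesh$coords))
  bd <- mesh$params$block_dims; h <- mesh$params$grid_spacing
  interior <- which(apply(mesh$coords, 1, function(p)
    all(p > h / 2 & p < bd - h / 2)))
  expect_lt(max(abs(f[interior, ])), 1e-8 * max(abs(f)))
})

test_that("1-D wavefront travels at sqrt(E/rho) within 2% and energy drifts < 1% of peak kinetic", {
  fx <- bar_fixture()
  m <- measure_bar_wave(fx)
  expect_rel_equal(m$speed, fx$c0, 0.02)
  expect_equal(nrow(m$history$events), 0)
  expect_lt(m$drift, 0.01 * m$peak_kinetic)
})

test_that("momentum is conserved through frictionless contact on an unconstrained mesh", {
  mesh <- build_mesh(tiny_geometry())
  mesh$region[] <- "IMPLANT"   # elastic everywhere, no deletion
  mesh$element_sets$IMPLANT <- seq_along(mesh$region)
  imp <- impactor(radius = 0.003, mass = 1e-4, velocity = c(0, 0, -2),
                  center = c(0.003, 0.003, 0.008 + 0.003 + 0.001))
  model <- fe_model(mesh, uniform_materials(E = 1e8, nu = 0.25, rho = 800),
                    fixed_nodes = integer(), imp = imp, allow_free = TRUE)
  hist <- fem_run(model, time_integration_params(t_end = 4e-4,
                                                 output_every = 50L))
  m <- lumped_mass(model)
  p_mesh <- colSums(hist$final$vel * m)
  p_imp <- imp$mass * hist$final$impactor_vel
  p0 <- imp$mass * imp$velocity
  expect_false(hist$final$impactor_active)  # the sphere bounced off and was removed
  expect_lt(max(abs(p_mesh + p_imp - p0)), 0.005 * sqrt(sum(p0^2)))
})

test_that("stiffness-proportional damping dissipates energy; zero damping does not", {
  fx <- bar_fixture(L = 0.02)
  damped <- fe_model(fx$mesh, uniform_materials(E = 1e9, nu = 0, rho = 1000),
                     fixed_nodes = integer(), allow_free = TRUE,
                     damping_beta = 2e-7)
  launch <- function(model) {
    st <- sim_state(model)
    z <- fx$mesh$coords[, 3]
    st$vel[, 3] <- ifelse(z < 0.003, cos(pi * z / 0.006)^2, 0)
    fem_run(model, time_integration_params(t_end = 1.2e-5, output_every = 5L),
            state = st, record_fields = FALSE)
  }
  h0 <- launch(fx$model)
  h1 <- launch(damped)
  en0 <- h0$energy$total_J; en1 <- h1$energy$total_J
  expect_lt(en1[length(en1) - 1], 0.9 * en1[2])     # damped: energy decays
  expect_rel_equal(en0[length(en0) - 1], en0[2], 1e-9)  # undamped: conserved
})

test_that("non-finite states are reported with the offending node", {
  mesh <- build_mesh(tiny_geometry())
  model <- fe_model(mesh, uniform_materials())
  st <- sim_state(model)
  st$disp[5, 1] <- NaN
  expect_error(fem_step(model, st, 1e-8), "non-finite")
})
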