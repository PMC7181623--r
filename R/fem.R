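# Explicit central-difference elastodynamics on linear (constant-strain)
# tetrahedra with lumped mass, clamped block faces, and a rigid frictionless
# spherical impactor coupled through penalty contact. The per-step primitives
# are exposed individually; production runs use a compiled loop with the
# identical update rule.

#' Rigid spherical impactor
#'
#' A rigid sphere with initial velocity, coupled to designated contact nodes
#' by frictionless penalty contact. The loading protocol forces the sphere to
#' be removed immediately after contact, so it is permanently deactivated at
#' the first genuine separation (a full gap with the sphere receding, i.e.
#' its velocity no longer pointing along the original approach direction) or
#' at the latest `max_contact_duration` after first touch, whichever comes
#' first. Literal removal at the instant of touch would transmit no impulse;
#' without the duration cap the sphere would keep plowing, turning the brief
#' impact into sustained penetration.
#'
#' @param radius sphere radius, m (default 7.5 mm, a 1.5 cm ball).
#' @param mass sphere mass, kg (default 15 g, the drop ball).
#' @param velocity length-3 initial velocity, m/s.
#' @param center length-3 initial center position, m (usually set by
#'   [place_impactor()]).
#' @param initial_gap nominal initial standoff from the implant surface, m
#'   (default 2 mm).
#' @param penalty_stiffness contact penalty stiffness, N/m; `NULL` auto-sets
#'   it from the stiffness of the elements adjacent to the contact nodes
#'   when the model is assembled.
#' @param max_contact_duration forced-removal time after first touch, s;
#'   `NULL` auto-sets one contact half-period `pi sqrt(mass / k)` of the
#'   sphere on its penalty spring when the model is assembled.
#' @param active logical.
#' @return object of class `oi_impactor`.
#' @export
impactor <- function(radius = 0.0075, mass = 0.015, velocity = c(0, 0, -1),
                     center = NULL, initial_gap = 0.002,
                     penalty_stiffness = NULL, max_contact_duration = NULL,
                     active = TRUE) {
  stopifnot(radius > 0, mass > 0, length(velocity) == 3, initial_gap >= 0)
  if (!is.null(penalty_stiffness) && penalty_stiffness <= 0)
    stop("penalty_stiffness must be > 0")
  if (!is.null(max_contact_duration) && max_contact_duration <= 0)
    stop("max_contact_duration must be > 0")
  structure(list(radius = radius, mass = mass,
                 velocity = as.numeric(velocity), center = center,
                 initial_gap = initial_gap,
                 penalty_stiffness = penalty_stiffness,
                 max_contact_duration = max_contact_duration,
                 active = isTRUE(active)), class = "oi_impactor")
}

#' Assemble a finite-element model
#'
#' Resolves per-element material constants from the mesh regions, precomputes
#' shape-function gradients, volumes and minimum altitudes, and (if an
#' impactor is attached without an explicit penalty stiffness) auto-sets the
#' contact penalty to 10x the stiffest nodal stiffness estimate `E h` of the
#' elements adjacent to the contact nodes.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param materials an [material_library()] (default
#'   [default_material_library()]).
#' @param fixed_nodes node indices clamped in all three directions; default
#'   the mesh's `FIXED` set. Must be nonempty unless `allow_free = TRUE`.
#' @param imp an [impactor()] or `NULL`.
#' @param contact_nodes candidate contact node indices; default the mesh's
#'   `IMPLANT_TOP` set (contact is defined between the sphere and the implant
#'   surface only).
#' @param allow_free permit an unconstrained mesh (used by momentum checks).
#' @param damping_beta stiffness-proportional damping coefficient, s
#'   (viscous stress `beta C : eps_dot` added to the force assembly only);
#'   default 0, no structural damping.
#' @return object of class `oi_fe_model`.
#' @export
fe_model <- function(mesh, materials = default_material_library(),
                     fixed_nodes = NULL, imp = NULL, contact_nodes = NULL,
                     allow_free = FALSE, damping_beta = 0) {
  stopifnot(inherits(mesh, "oi_mesh"),
            inherits(materials, "oi_material_library"))
  if (is.null(fixed_nodes)) fixed_nodes <- mesh$node_sets$FIXED
  if (!length(fixed_nodes) && !allow_free)
    stop("fixed_nodes must be nonempty")
  if (is.null(contact_nodes)) contact_nodes <- mesh$node_sets$IMPLANT_TOP

  ne <- nrow(mesh$tets)
  lambda <- mu <- rho <- yield <- Emod <- numeric(ne)
  for (rg in c("IMPLANT", "CORTICAL", "CANCELLOUS")) {
    idx <- which(mesh$region == rg)
    if (!length(idx)) next
    lm <- lame_parameters(materials[[rg]]$elastic)
    lambda[idx] <- lm["lambda"]; mu[idx] <- lm["mu"]
    rho[idx] <- materials[[rg]]$elastic$rho
    Emod[idx] <- materials[[rg]]$elastic$E
    yield[idx] <- if (is.null(materials[[rg]]$failure)) Inf else
      materials[[rg]]$failure$yield_strength
  }
  lambda <- lambda * mesh$modulus_scale
  mu <- mu * mesh$modulus_scale

  pre <- cpp_tet_precompute(mesh$coords, mesh$tets - 1L)
  if (any(pre$vol <= 0)) stop("mesh contains non-positive tet volumes")
  altitudes <- cpp_min_altitudes(mesh$coords, mesh$tets - 1L)
  wave_speed <- sqrt((lambda + 2 * mu) / rho)
  mass <- as.numeric(cpp_lumped_mass(pre$vol, mesh$tets - 1L, rho,
                                     nrow(mesh$coords)))

  if (!is.null(imp)) {
    stopifnot(inherits(imp, "oi_impactor"))
    if (is.null(imp$penalty_stiffness)) {
      adj <- which(apply(matrix(mesh$tets %in% contact_nodes, ncol = 4), 1, any))
      imp$penalty_stiffness <- 10 * max(Emod[adj] * pre$vol[adj]^(1 / 3))
    }
    if (is.null(imp$max_contact_duration))
      imp$max_contact_duration <- pi * sqrt(imp$mass / imp$penalty_stiffness)
  }

  structure(list(mesh = mesh, materials = materials,
                 fixed_nodes = as.integer(fixed_nodes),
                 contact_nodes = as.integer(contact_nodes),
                 impactor = imp,
                 lambda = lambda, mu = mu, rho = rho, yield = yield,
                 grads = pre$grads, vol = pre$vol, altitudes = altitudes,
                 wave_speed = wave_speed, nodal_mass = mass,
                 damping_beta = damping_beta),
            class = "oi_fe_model")
}

#' Lumped nodal masses
#'
#' Each element's mass `rho V` is distributed equally to its 4 nodes, so the
#' total nodal mass equals the total element mass exactly. Mass is retained
#' when elements are deleted.
#'
#' @param model an [fe_model()].
#' @return numeric vector of per-node masses, kg.
#' @export
lumped_mass <- function(model) model$nodal_mass

#' Stress in a single element for a given displacement field
#'
#' Small-strain kinematics: `eps = sym(grad u)` from the linear shape
#' functions (constant over the element), `sigma = lambda tr(eps) I +
#' 2 mu eps`.
#'
#' @param model an [fe_model()].
#' @param element element index (1-based).
#' @param disp N x 3 nodal displacement matrix, m.
#' @return 3 x 3 symmetric Cauchy stress, Pa.
#' @export
element_stress <- function(model, element, disp) {
  s <- element_stresses(model, disp)[element, ]
  matrix(c(s[1], s[4], s[6],
           s[4], s[2], s[5],
           s[6], s[5], s[3]), 3, 3)
}

#' Stresses in all elements
#'
#' @inheritParams element_stress
#' @param active logical per-element flags; inactive elements report zero.
#' @return E x 6 matrix in Voigt order `[11, 22, 33, 12, 23, 31]`, Pa.
#' @export
element_stresses <- function(model, disp, active = NULL) {
  if (is.null(active)) active <- rep(TRUE, nrow(model$mesh$tets))
  cpp_element_stresses(model$grads, model$mesh$tets - 1L, disp,
                       model$lambda, model$mu, as.integer(active))
}

#' Internal nodal forces
#'
#' The force exerted on the nodes by the element stresses, i.e. minus the
#' gradient of the total strain energy with respect to the nodal
#' displacements. Deactivated elements contribute nothing.
#'
#' @inheritParams element_stresses
#' @return N x 3 force matrix, N.
#' @export
internal_forces <- function(model, disp, active = NULL) {
  if (is.null(active)) active <- rep(TRUE, nrow(model$mesh$tets))
  stress <- element_stresses(model, disp, active)
  cpp_internal_forces(model$grads, model$vol, model$mesh$tets - 1L, stress,
                      as.integer(active), nrow(model$mesh$coords))
}

#' Stable explicit time step (CFL limit)
#'
#' `cfl_factor` times the minimum over active elements of (minimum tet
#' altitude / dilatational wave speed of its material). With
#' stiffness-proportional damping the limit shrinks by the standard factor
#' `sqrt(1 + xi^2) - xi`, `xi = beta omega_e / 2` at the element frequency
#' `omega_e = 2 c / h`. When the model carries an impactor the
#' penalty-contact frequency also bounds the step: `cfl_factor * 2 / omega`
#' with `omega = sqrt(k (1/m_min + 1/M))`, `m_min` the lightest contact node.
#'
#' @param model an [fe_model()].
#' @param active logical per-element flags (default all active).
#' @param cfl_factor safety factor in (0, 1], default 0.5.
#' @return time step in s.
#' @export
stable_dt <- function(model, active = NULL, cfl_factor = 0.5) {
  stopifnot(cfl_factor > 0, cfl_factor <= 1)
  if (is.null(active)) active <- rep(TRUE, nrow(model$mesh$tets))
  if (!any(active)) stop("no active elements")
  per_elem <- model$altitudes[active] / model$wave_speed[active]
  if (model$damping_beta > 0) {
    xi <- model$damping_beta * model$wave_speed[active] /
      model$altitudes[active]             # beta * omega_e / 2, omega_e = 2c/h
    per_elem <- per_elem * (sqrt(1 + xi^2) - xi)
  }
  dt <- cfl_factor * min(per_elem)
  imp <- model$impactor
  if (!is.null(imp) && isTRUE(imp$active)) {
    m_min <- min(model$nodal_mass[model$contact_nodes])
    omega <- sqrt(imp$penalty_stiffness * (1 / m_min + 1 / imp$mass))
    dt <- min(dt, cfl_factor * 2 / omega)
  }
  dt
}

#' Initial simulation state
#'
#' @param model an [fe_model()].
#' @return object of class `oi_sim_state`: time, nodal kinematics, element
#'   stresses, per-element active flags, and impactor position/velocity.
#' @export
sim_state <- function(model) {
  n <- nrow(model$mesh$coords); e <- nrow(model$mesh$tets)
  imp <- model$impactor
  structure(list(time = 0,
                 disp = matrix(0, n, 3), vel = matrix(0, n, 3),
                 acc = matrix(0, n, 3),
                 stress = matrix(0, e, 6),
                 active = rep(TRUE, e),
                 impactor_center = if (!is.null(imp)) imp$center,
                 impactor_vel = if (!is.null(imp)) imp$velocity,
                 impactor_active = if (!is.null(imp)) imp$active else FALSE,
                 approach_dir = if (!is.null(imp) && sum(imp$velocity^2) > 0)
                   imp$velocity / sqrt(sum(imp$velocity^2)),
                 touched = FALSE, t_touch = NA_real_, t_sep = NA_real_),
            class = "oi_sim_state")
}

#' Frictionless penalty contact forces between the sphere and contact nodes
#'
#' For every contact-candidate node penetrating the sphere by `g > 0`, a
#' normal force `k g` acts along the outward sphere-surface normal (no
#' tangential component); the equal-and-opposite resultant acts on the
#' sphere.
#'
#' @param model an [fe_model()] carrying an impactor.
#' @param state an `oi_sim_state`.
#' @return list with `forces` (N x 3 nodal forces), `reaction` (length-3
#'   force on the sphere), `any_contact`, `penalty_energy`.
#' @export
contact_force <- function(model, state) {
  imp <- model$impactor
  if (is.null(imp)) stop("model has no impactor")
  if (!isTRUE(state$impactor_active))
    return(list(forces = matrix(0, nrow(model$mesh$coords), 3),
                reaction = c(0, 0, 0), any_contact = FALSE,
                penalty_energy = 0))
  res <- cpp_contact_force(model$mesh$coords, state$disp,
                           model$contact_nodes - 1L, state$impactor_center,
                           imp$radius, imp$penalty_stiffness,
                           nrow(model$mesh$coords))
  res$reaction <- as.numeric(res$reaction)
  res
}

#' Advance the state by one explicit central-difference step
#'
#' Accelerations `a = M^-1 (f_int + f_contact)` from the state's current
#' displacement; velocities and displacements advanced by the central
#' difference (v += dt a; u += dt v); fixed nodes clamped to zero; the sphere
#' advanced under its contact reaction; element stresses refreshed at the
#' new displacement. Once contact has occurred and every gap has then
#' reopened, the impactor is deactivated permanently. Failure is not applied
#' here; see [apply_failure()].
#'
#' @param model an [fe_model()].
#' @param state an `oi_sim_state`.
#' @param dt time step, s; must not exceed [stable_dt()].
#' @return the advanced `oi_sim_state`.
#' @export
fem_step <- function(model, state, dt) {
  stopifnot(inherits(state, "oi_sim_state"), dt > 0)
  active <- state$active
  stress <- element_stresses(model, state$disp, active)
  fstress <- stress
  if (model$damping_beta > 0)
    fstress <- stress + model$damping_beta *
      element_stresses(model, state$vel, active)
  f <- cpp_internal_forces(model$grads, model$vol, model$mesh$tets - 1L,
                           fstress, as.integer(active),
                           nrow(model$mesh$coords))
  reaction <- c(0, 0, 0); any_contact <- FALSE; removed_now <- FALSE
  if (!is.null(model$impactor) && isTRUE(state$impactor_active)) {
    cf <- contact_force(model, state)
    any_contact <- cf$any_contact
    if (any_contact && !state$touched) {
      state$touched <- TRUE; state$t_touch <- state$time
    }
    receding <- is.null(state$approach_dir) ||
      sum(state$impactor_vel * state$approach_dir) <= 0
    cap <- model$impactor$max_contact_duration
    overdue <- state$touched && !is.null(cap) &&
      state$time - state$t_touch >= cap
    if (state$touched && ((!any_contact && receding) || overdue)) {
      removed_now <- TRUE   # removal is decided before forces are applied
    } else {
      f <- f + cf$forces
      reaction <- cf$reaction
    }
  }
  acc <- f / model$nodal_mass
  vel <- state$vel + dt * acc
  disp <- state$disp + dt * vel
  fx <- model$fixed_nodes
  if (length(fx)) { acc[fx, ] <- 0; vel[fx, ] <- 0; disp[fx, ] <- 0 }
  if (!all(is.finite(disp))) {
    bad <- which(!is.finite(rowSums(disp)))[1]
    stop("non-finite state detected at node ", bad, " (t = ",
         state$time + dt, ")")
  }
  state$acc <- acc; state$vel <- vel; state$disp <- disp
  if (!is.null(model$impactor) && isTRUE(state$impactor_active)) {
    if (removed_now) {
      state$impactor_active <- FALSE
      state$t_sep <- state$time
    } else {
      state$impactor_vel <- state$impactor_vel +
        dt * reaction / model$impactor$mass
      state$impactor_center <- state$impactor_center + dt * state$impactor_vel
    }
  }
  state$time <- state$time + dt
  state$stress <- element_stresses(model, state$disp, state$active)
  state
}

#' Time-integration parameters
#'
#' @param t_end hard cap on simulated time, s. With an impactor the run ends
#'   earlier, `post_window_factor` contact durations after the sphere
#'   separates or after the last damage event, whichever is later, so the
#'   delayed post-unloading stress-wave damage is fully captured.
#' @param cfl_factor stable-step safety factor in (0, 1].
#' @param output_every snapshot interval in steps.
#' @param post_window_factor multiple of the contact duration simulated after
#'   the sphere separates (default 5).
#' @return object of class `oi_time_params`.
#' @export
time_integration_params <- function(t_end = 5e-4, cfl_factor = 0.5,
                                    output_every = 10L,
                                    post_window_factor = 5) {
  stopifnot(t_end >= 0, cfl_factor > 0, cfl_factor <= 1, output_every >= 1)
  structure(list(t_end = t_end, cfl_factor = cfl_factor,
                 output_every = as.integer(output_every),
                 post_window_factor = post_window_factor),
            class = "oi_time_params")
}

#' Run an explicit dynamic simulation
#'
#' Compiled loop of stress update / force assembly / central-difference step
#' / failure application until the end of the post-unloading window (or
#' `t_end`), with snapshots every `output_every` steps: energy ledger
#' (kinetic + strain + penalty, plus the sphere's kinetic energy while
#' active), cumulative deletion count, impactor trajectory, and (if
#' `record_fields`) per-element von Mises and per-node displacement-magnitude
#' histories. If the mesh starts at rest, the sphere's approach is
#' fast-forwarded analytically to just before first touch. The ledger's
#' kinetic entry is the staggered leapfrog product (exactly conserved, with
#' the strain energy, for linear motion); the terminal snapshot necessarily
#' uses instantaneous velocities instead.
#'
#' @param model an [fe_model()].
#' @param params an [time_integration_params()].
#' @param state optional initial `oi_sim_state` (default [sim_state()]).
#' @param record_fields store field histories for probing (default `TRUE`).
#' @param dt optional explicit time step; default [stable_dt()] at the
#'   model's initial active set.
#' @return object of class `oi_history`: `final` state, `events` data frame
#'   (element, region, time_s, vm_Pa), `snapshots`, `energy` data frame,
#'   `dt`, `t_touch`, `t_sep`, `n_steps`, and the `mesh`.
#' @export
fem_run <- function(model, params = time_integration_params(), state = NULL,
                    record_fields = TRUE, dt = NULL) {
  stopifnot(inherits(model, "oi_fe_model"), inherits(params, "oi_time_params"))
  if (is.null(state)) state <- sim_state(model)
  if (is.null(dt)) dt <- stable_dt(model, state$active, params$cfl_factor)
  imp <- model$impactor
  has_imp <- !is.null(imp) && isTRUE(state$impactor_active)
  if (has_imp && is.null(state$impactor_center))
    stop("impactor has no center; use place_impactor() or set center")
  res <- cpp_run(
    model$mesh$coords, model$mesh$tets - 1L, model$grads, model$vol,
    model$lambda, model$mu, model$rho, model$yield,
    model$fixed_nodes - 1L, model$contact_nodes - 1L,
    if (has_imp) as.numeric(state$impactor_center) else c(0, 0, 0),
    if (has_imp) as.numeric(state$impactor_vel) else c(0, 0, 0),
    if (has_imp) imp$radius else 1, if (has_imp) imp$mass else 1,
    if (has_imp) imp$penalty_stiffness else 0, has_imp,
    if (has_imp) imp$max_contact_duration else Inf,
    state$disp, state$vel, as.integer(state$active),
    dt, state$time, params$t_end, params$post_window_factor,
    params$output_every, record_fields, model$damping_beta)

  final <- state
  final$time <- res$time
  final$disp <- res$disp; final$vel <- res$vel; final$acc <- res$acc
  final$stress <- res$stress
  final$active <- as.logical(res$active)
  final$impactor_center <- as.numeric(res$impactor_center)
  final$impactor_vel <- as.numeric(res$impactor_vel)
  final$impactor_active <- res$impactor_active
  final$t_touch <- res$t_touch; final$t_sep <- res$t_sep
  final$touched <- is.finite(res$t_touch)

  elems <- as.integer(res$event_elem)
  events <- data.frame(element = elems,
                       region = model$mesh$region[elems],
                       time_s = as.numeric(res$event_time),
                       vm_Pa = as.numeric(res$event_vm))
  sn <- res$snapshots
  energy <- data.frame(time_s = as.numeric(sn$time),
                       kinetic_J = sn$energy[, 1], strain_J = sn$energy[, 2],
                       penalty_J = sn$energy[, 3],
                       impactor_J = sn$energy[, 4], total_J = sn$energy[, 5])
  structure(list(final = final, events = events, energy = energy,
                 snapshots = sn, dt = res$dt, n_steps = res$n_steps,
                 t_touch = res$t_touch, t_sep = res$t_sep,
                 mesh = model$mesh), class = "oi_history")
}

#' @export
print.oi_history <- function(x, ...) {
  cat(sprintf("explicit dynamics history: %g steps of dt = %.3g s to t = %.3g s\n",
              x$n_steps, x$dt, x$final$time))
  cat(sprintf("  deletions: %d (%s)\n", nrow(x$events),
              paste(sprintf("%s=%d", names(table(x$events$region)),
                            table(x$events$region)), collapse = ", ")))
  if (is.finite(x$t_touch))
    cat(sprintf("  contact: %.3g s to %.3g s\n", x$t_touch, x$t_sep))
  invisible(x)
}

#' Export snapshot fields as a legacy VTK series
#'
#' Writes one VTK file per stored snapshot with von Mises stress and active
#' flag as cell data and displacement magnitude as point data (requires the
#' run to have been made with `record_fields = TRUE`).
#'
#' @param history an [fem_run()] result.
#' @param dir output directory.
#' @param basename file name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_vtk_series <- function(history, dir, basename = "snapshot") {
  if (is.null(history$snapshots$vm))
    stop("history has no field snapshots; run with record_fields = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- history$mesh
  paths <- character()
  for (i in seq_along(history$snapshots$time)) {
    p <- file.path(dir, sprintf("%s_%04d.vtk", basename, i - 1L))
    write_vtk(mesh, p, cell_data = list(von_mises = history$snapshots$vm[, i]))
    paths <- c(paths, p)
  }
  invisible(paths)
}
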