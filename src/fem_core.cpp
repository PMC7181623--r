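// Explicit central-difference elastodynamics on constant-strain tetrahedra.
//
// Conventions shared with the R layer:
//  * node coordinates in m, SI units throughout
//  * tets are 0-based here (the R layer stores 1-based and converts)
//  * stress/strain in Voigt order [11, 22, 33, 12, 23, 31], tensor (not
//    engineering) shear components
//  * "internal force" is the force exerted on the nodes by the stress
//    field, i.e. minus the gradient of total strain energy
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Shape-function gradients (constant over a linear tet) and signed volumes.
// grads: E x 12, rows [dN0x dN0y dN0z dN1x ... dN3z]; vol: signed volume.
// [[Rcpp::export]]
List cpp_tet_precompute(const arma::mat& coords, const arma::imat& tets) {
  const arma::uword ne = tets.n_rows;
  arma::mat grads(ne, 12);
  arma::vec vol(ne);
  for (arma::uword e = 0; e < ne; ++e) {
    arma::uword i0 = tets(e, 0), i1 = tets(e, 1), i2 = tets(e, 2), i3 = tets(e, 3);
    arma::rowvec3 p0 = coords.row(i0);
    arma::mat33 J;
    J.col(0) = (coords.row(i1) - p0).t();
    J.col(1) = (coords.row(i2) - p0).t();
    J.col(2) = (coords.row(i3) - p0).t();
    double detJ = arma::det(J);
    vol(e) = detJ / 6.0;
    if (std::abs(detJ) < 1e-300)
      stop("degenerate tetrahedron (zero volume) at element %d", (int)e + 1);
    arma::mat33 Jinv = arma::inv(J);
    // rows of Jinv are grad(L1), grad(L2), grad(L3); grad(L0) = -sum
    arma::rowvec3 g1 = Jinv.row(0), g2 = Jinv.row(1), g3 = Jinv.row(2);
    arma::rowvec3 g0 = -(g1 + g2 + g3);
    grads(e, arma::span(0, 2))  = g0;
    grads(e, arma::span(3, 5))  = g1;
    grads(e, arma::span(6, 8))  = g2;
    grads(e, arma::span(9, 11)) = g3;
  }
  return List::create(_["grads"] = grads, _["vol"] = vol);
}

static inline void element_strain(const arma::mat& grads, const arma::imat& tets,
                                  const arma::mat& disp, arma::uword e,
                                  arma::vec6& eps) {
  arma::mat33 H(arma::fill::zeros);
  for (int a = 0; a < 4; ++a) {
    arma::uword n = tets(e, a);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        H(i, j) += disp(n, i) * grads(e, 3 * a + j);
  }
  eps(0) = H(0, 0);
  eps(1) = H(1, 1);
  eps(2) = H(2, 2);
  eps(3) = 0.5 * (H(0, 1) + H(1, 0));
  eps(4) = 0.5 * (H(1, 2) + H(2, 1));
  eps(5) = 0.5 * (H(2, 0) + H(0, 2));
}

static inline void hooke(const arma::vec6& eps, double lam, double mu,
                         arma::vec6& sig) {
  double tr = eps(0) + eps(1) + eps(2);
  sig(0) = lam * tr + 2.0 * mu * eps(0);
  sig(1) = lam * tr + 2.0 * mu * eps(1);
  sig(2) = lam * tr + 2.0 * mu * eps(2);
  sig(3) = 2.0 * mu * eps(3);
  sig(4) = 2.0 * mu * eps(4);
  sig(5) = 2.0 * mu * eps(5);
}

static inline double vm_of(const arma::vec6& s) {
  double d01 = s(0) - s(1), d12 = s(1) - s(2), d20 = s(2) - s(0);
  return std::sqrt(0.5 * (d01 * d01 + d12 * d12 + d20 * d20) +
                   3.0 * (s(3) * s(3) + s(4) * s(4) + s(5) * s(5)));
}

// Per-element Cauchy stress from a nodal displacement field. Inactive
// elements report zero stress.
// [[Rcpp::export]]
arma::mat cpp_element_stresses(const arma::mat& grads, const arma::imat& tets,
                               const arma::mat& disp, const arma::vec& lambda,
                               const arma::vec& mu, const arma::uvec& active) {
  const arma::uword ne = tets.n_rows;
  arma::mat stress(ne, 6, arma::fill::zeros);
  arma::vec6 eps, sig;
  for (arma::uword e = 0; e < ne; ++e) {
    if (!active(e)) continue;
    element_strain(grads, tets, disp, e, eps);
    hooke(eps, lambda(e), mu(e), sig);
    stress.row(e) = sig.t();
  }
  return stress;
}

// Nodal forces exerted by the element stresses (= -dU/du). Inactive
// elements contribute nothing.
// [[Rcpp::export]]
arma::mat cpp_internal_forces(const arma::mat& grads, const arma::vec& vol,
                              const arma::imat& tets, const arma::mat& stress,
                              const arma::uvec& active, int nnode) {
  arma::mat f(nnode, 3, arma::fill::zeros);
  const arma::uword ne = tets.n_rows;
  for (arma::uword e = 0; e < ne; ++e) {
    if (!active(e)) continue;
    arma::mat33 S = {{stress(e, 0), stress(e, 3), stress(e, 5)},
                     {stress(e, 3), stress(e, 1), stress(e, 4)},
                     {stress(e, 5), stress(e, 4), stress(e, 2)}};
    double V = vol(e);
    for (int a = 0; a < 4; ++a) {
      arma::uword n = tets(e, a);
      for (int i = 0; i < 3; ++i) {
        double fi = 0.0;
        for (int j = 0; j < 3; ++j) fi += S(i, j) * grads(e, 3 * a + j);
        f(n, i) -= V * fi;
      }
    }
  }
  return f;
}

// [[Rcpp::export]]
arma::vec cpp_lumped_mass(const arma::vec& vol, const arma::imat& tets,
                          const arma::vec& rho, int nnode) {
  arma::vec m(nnode, arma::fill::zeros);
  for (arma::uword e = 0; e < tets.n_rows; ++e) {
    if (vol(e) <= 0.0) stop("non-positive element volume at element %d", (int)e + 1);
    double share = rho(e) * vol(e) / 4.0;
    for (int a = 0; a < 4; ++a) m(tets(e, a)) += share;
  }
  return m;
}

// Minimum altitude per tet: 3 V / max face area.
// [[Rcpp::export]]
arma::vec cpp_min_altitudes(const arma::mat& coords, const arma::imat& tets) {
  const arma::uword ne = tets.n_rows;
  arma::vec h(ne);
  const int faces[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
  for (arma::uword e = 0; e < ne; ++e) {
    arma::vec3 p[4];
    for (int a = 0; a < 4; ++a) p[a] = coords.row(tets(e, a)).t();
    double V = std::abs(arma::dot(arma::cross(p[1] - p[0], p[2] - p[0]), p[3] - p[0])) / 6.0;
    double amax = 0.0;
    for (int fidx = 0; fidx < 4; ++fidx) {
      arma::vec3 u = p[faces[fidx][1]] - p[faces[fidx][0]];
      arma::vec3 v = p[faces[fidx][2]] - p[faces[fidx][0]];
      double A = 0.5 * arma::norm(arma::cross(u, v));
      if (A > amax) amax = A;
    }
    h(e) = 3.0 * V / amax;
  }
  return h;
}

// Penalty contact between a rigid sphere and a set of candidate nodes.
// Returns nodal forces (full N x 3), the reaction on the sphere, whether any
// node penetrates, and the stored penalty energy.
// [[Rcpp::export]]
List cpp_contact_force(const arma::mat& coords, const arma::mat& disp,
                       const arma::ivec& contact_nodes, const arma::vec& center,
                       double radius, double k, int nnode) {
  arma::mat f(nnode, 3, arma::fill::zeros);
  arma::vec3 reaction(arma::fill::zeros);
  arma::vec3 c = {center(0), center(1), center(2)};
  bool any = false;
  double pen_energy = 0.0;
  for (arma::uword ii = 0; ii < contact_nodes.n_elem; ++ii) {
    arma::uword n = contact_nodes(ii);
    arma::vec3 p = coords.row(n).t() + disp.row(n).t();
    arma::vec3 r = p - c;
    double dist = arma::norm(r);
    double pen = radius - dist;
    if (pen > 0.0 && dist > 1e-300) {
      any = true;
      arma::vec3 nrm = r / dist;  // outward surface normal at the node
      arma::vec3 fn = k * pen * nrm;
      f.row(n) += fn.t();
      reaction -= fn;
      pen_energy += 0.5 * k * pen * pen;
    }
  }
  return List::create(_["forces"] = f, _["reaction"] = reaction,
                      _["any_contact"] = any, _["penalty_energy"] = pen_energy);
}

// Full explicit run: loop of stress update / force assembly / central
// difference step / failure check, with damage-event logging, energy ledger,
// probe field histories and rigid-impactor bookkeeping.
//
// Impactor removal rule ("removed immediately after contact"): the sphere is
// deactivated permanently at the first full separation at which it is
// receding, or forcibly once `contact_cap` has elapsed since first touch.
//
// If the mesh starts at rest the approach phase is skipped analytically
// (the sphere travels in a straight line until just before first touch).
// [[Rcpp::export]]
List cpp_run(const arma::mat& coords, const arma::imat& tets,
             const arma::mat& grads, const arma::vec& vol,
             const arma::vec& lambda, const arma::vec& mu, const arma::vec& rho,
             const arma::vec& yield_strength, const arma::ivec& fixed_nodes,
             const arma::ivec& contact_nodes,
             arma::vec impactor_center, arma::vec impactor_vel,
             double impactor_radius, double impactor_mass, double penalty_k,
             bool impactor_active, double contact_cap,
             arma::mat disp, arma::mat vel, arma::uvec active,
             double dt, double t0, double t_max, double post_factor,
             int output_every, bool record_fields, double damping_beta) {
  const arma::uword ne = tets.n_rows;
  const int nnode = coords.n_rows;
  arma::vec mass = cpp_lumped_mass(vol, tets, rho, nnode);

  arma::mat stress(ne, 6, arma::fill::zeros);
  arma::vec elem_energy(ne, arma::fill::zeros);
  arma::vec vm(ne, arma::fill::zeros);
  arma::mat acc(nnode, 3, arma::fill::zeros);

  double t = t0;
  bool touched = false, separated = false;
  double t_touch = NA_REAL, t_sep = NA_REAL;
  // approach direction: removal requires the sphere to be receding, so a
  // momentary gap while it is still flying into the implant does not count
  arma::vec approach_dir = impactor_vel;
  double av_norm = arma::norm(approach_dir);
  if (av_norm > 0) approach_dir /= av_norm;

  // analytic fast-forward through the approach phase
  bool at_rest = (arma::abs(disp).max() == 0.0) && (arma::abs(vel).max() == 0.0);
  if (impactor_active && at_rest && arma::norm(impactor_vel) > 0.0) {
    double t_hit = arma::datum::inf;
    arma::vec3 c = {impactor_center(0), impactor_center(1), impactor_center(2)};
    arma::vec3 w = {impactor_vel(0), impactor_vel(1), impactor_vel(2)};
    for (arma::uword ii = 0; ii < contact_nodes.n_elem; ++ii) {
      arma::vec3 p = coords.row(contact_nodes(ii)).t();
      arma::vec3 d = p - c;
      // |d - w s| = radius
      double a = arma::dot(w, w), b = -2.0 * arma::dot(d, w);
      double cc = arma::dot(d, d) - impactor_radius * impactor_radius;
      double disc = b * b - 4.0 * a * cc;
      if (disc < 0.0) continue;
      double s = (-b - std::sqrt(disc)) / (2.0 * a);
      if (s > 0.0 && s < t_hit) t_hit = s;
    }
    if (std::isfinite(t_hit) && t_hit > 2.0 * dt) {
      long nskip = (long)std::floor((t_hit - dt) / dt);
      t += nskip * dt;
      t_max += nskip * dt;  // the approach does not consume the time budget
      impactor_center += nskip * dt * impactor_vel;
    }
  }

  long max_steps = (long)std::ceil((t_max - t) / dt) + 2;
  int max_snaps = (int)(max_steps / output_every) + 3;
  arma::vec snap_t(max_snaps);
  arma::mat snap_energy(max_snaps, 5);   // kinetic, strain, penalty, impactor, total
  arma::imat snap_counts(max_snaps, 1);  // cumulative deletions
  arma::mat snap_imp(max_snaps, 7);      // center, vel, active flag
  arma::mat vm_hist, dispmag_hist;
  if (record_fields) {
    vm_hist.set_size(ne, max_snaps);
    dispmag_hist.set_size(nnode, max_snaps);
  }
  int nsnap = 0;

  std::vector<int> ev_elem;
  std::vector<double> ev_time, ev_vm;

  long step = 0;
  bool blown_up = false;
  std::string blow_msg;

  double t_last_event = -arma::datum::inf;
  while (true) {
    // after separation, run on until the damage has quiesced: no deletion
    // for post_factor contact durations (the post-unloading window exists to
    // capture delayed stress-wave damage)
    double t_end = t_max;
    if (separated) {
      double hold = std::max(t_sep, t_last_event);
      t_end = std::min(t_max, hold + post_factor * (t_sep - t_touch));
    }

    // stress + strain energy for active elements (state at time t)
    arma::vec6 eps, sig;
    double strain_energy = 0.0;
    for (arma::uword e = 0; e < ne; ++e) {
      if (!active(e)) { vm(e) = 0.0; elem_energy(e) = 0.0; stress.row(e).zeros(); continue; }
      element_strain(grads, tets, disp, e, eps);
      hooke(eps, lambda(e), mu(e), sig);
      stress.row(e) = sig.t();
      vm(e) = vm_of(sig);
      elem_energy(e) = 0.5 * vol(e) *
        (sig(0) * eps(0) + sig(1) * eps(1) + sig(2) * eps(2) +
         2.0 * (sig(3) * eps(3) + sig(4) * eps(4) + sig(5) * eps(5)));
      strain_energy += elem_energy(e);
    }

    bool finished = (t >= t_end || step >= max_steps || blown_up);

    // forces at time t
    arma::mat f(nnode, 3);
    arma::vec3 reaction(arma::fill::zeros);
    bool any_contact = false;
    double pen_energy = 0.0;
    if (!finished) {
      if (damping_beta > 0.0) {
        // stiffness-proportional damping: viscous stress beta * C : eps_dot
        // enters the force assembly only (not the failure criterion)
        arma::mat fstress = stress;
        arma::vec6 epsd, sigd;
        for (arma::uword e = 0; e < ne; ++e) {
          if (!active(e)) continue;
          element_strain(grads, tets, vel, e, epsd);
          hooke(epsd, lambda(e), mu(e), sigd);
          fstress.row(e) += damping_beta * sigd.t();
        }
        f = cpp_internal_forces(grads, vol, tets, fstress, active, nnode);
      } else {
        f = cpp_internal_forces(grads, vol, tets, stress, active, nnode);
      }
      if (impactor_active) {
        arma::vec3 c = {impactor_center(0), impactor_center(1), impactor_center(2)};
        arma::mat fc(nnode, 3, arma::fill::zeros);
        for (arma::uword ii = 0; ii < contact_nodes.n_elem; ++ii) {
          arma::uword n = contact_nodes(ii);
          arma::vec3 p = coords.row(n).t() + disp.row(n).t();
          arma::vec3 r = p - c;
          double dist = arma::norm(r);
          double pen = impactor_radius - dist;
          if (pen > 0.0 && dist > 1e-300) {
            any_contact = true;
            arma::vec3 nrm = r / dist;
            fc.row(n) += (penalty_k * pen * nrm).t();
            reaction -= penalty_k * pen * nrm;
            pen_energy += 0.5 * penalty_k * pen * pen;
          }
        }
        if (any_contact && !touched) { touched = true; t_touch = t; }
        // "removed immediately after contact": gone at the first genuine
        // separation (sphere receding), or forcibly after one contact
        // half-period, whichever comes first. Decided before the forces are
        // applied, so removal never transfers a one-sided impulse.
        bool bounced = !any_contact &&
          arma::dot(impactor_vel, approach_dir) <= 0.0;
        if (touched && (bounced || t - t_touch >= contact_cap)) {
          impactor_active = false;
          separated = true;
          t_sep = t;
          reaction.zeros();
          pen_energy = 0.0;
        } else {
          f += fc;
        }
      }
    }

    // central-difference update; kinetic energy recorded as the staggered
    // product 1/2 m v_{n-1/2} . v_{n+1/2}, which together with the strain
    // energy at u_n is the conserved discrete energy of the leapfrog scheme
    double kin = 0.0, imp_kin = 0.0;
    if (!finished) {
      for (int n = 0; n < nnode; ++n) {
        double m = mass(n);
        for (int i = 0; i < 3; ++i) {
          double a = f(n, i) / m;
          acc(n, i) = a;
          double v_old = vel(n, i);
          double v_new = v_old + dt * a;
          vel(n, i) = v_new;
          disp(n, i) += dt * v_new;
          kin += 0.5 * m * v_old * v_new;
        }
      }
      for (arma::uword ii = 0; ii < fixed_nodes.n_elem; ++ii) {
        arma::uword n = fixed_nodes(ii);
        for (int i = 0; i < 3; ++i) { acc(n, i) = 0; vel(n, i) = 0; disp(n, i) = 0; }
      }
      if (impactor_active) {
        arma::vec v_old = impactor_vel;
        impactor_vel += dt * (reaction / impactor_mass);
        impactor_center += dt * impactor_vel;
        imp_kin = 0.5 * impactor_mass * arma::dot(v_old, impactor_vel);
      }
    } else {
      // ledger entries for the final snapshot
      for (int n = 0; n < nnode; ++n)
        for (int i = 0; i < 3; ++i)
          kin += 0.5 * mass(n) * vel(n, i) * vel(n, i);
      if (impactor_active)
        imp_kin = 0.5 * impactor_mass * arma::dot(impactor_vel, impactor_vel);
    }

    if ((step % output_every == 0 || finished) && nsnap < max_snaps) {
      snap_t(nsnap) = t;
      snap_energy(nsnap, 0) = kin;
      snap_energy(nsnap, 1) = strain_energy;
      snap_energy(nsnap, 2) = pen_energy;
      snap_energy(nsnap, 3) = imp_kin;
      snap_energy(nsnap, 4) = kin + strain_energy + pen_energy + imp_kin;
      snap_counts(nsnap, 0) = (int)ev_elem.size();
      snap_imp(nsnap, 0) = impactor_center(0);
      snap_imp(nsnap, 1) = impactor_center(1);
      snap_imp(nsnap, 2) = impactor_center(2);
      snap_imp(nsnap, 3) = impactor_vel(0);
      snap_imp(nsnap, 4) = impactor_vel(1);
      snap_imp(nsnap, 5) = impactor_vel(2);
      snap_imp(nsnap, 6) = impactor_active ? 1.0 : 0.0;
      if (record_fields) {
        vm_hist.col(nsnap) = vm;
        for (int n = 0; n < nnode; ++n)
          dispmag_hist(n, nsnap) = arma::norm(disp.row(n));
      }
      ++nsnap;
    }

    if (finished) break;

    t += dt;
    ++step;

    // failure: bone elements whose von Mises stress reached yield are
    // deleted (stiffness removed, mass retained); irreversible
    for (arma::uword e = 0; e < ne; ++e) {
      if (active(e) && std::isfinite(yield_strength(e)) && vm(e) >= yield_strength(e)) {
        active(e) = 0;
        ev_elem.push_back((int)e + 1);
        ev_time.push_back(t);
        ev_vm.push_back(vm(e));
        t_last_event = t;
      }
    }

    if (step % 50 == 0 && !disp.is_finite()) {
      blown_up = true;
      blow_msg = "non-finite displacement detected at t = " + std::to_string(t);
    }
  }

  if (blown_up) stop(blow_msg);

  arma::imat events((int)ev_elem.size(), 1);
  arma::vec ev_t((int)ev_time.size()), ev_s((int)ev_vm.size());
  for (size_t i = 0; i < ev_elem.size(); ++i) {
    events(i, 0) = ev_elem[i];
    ev_t(i) = ev_time[i];
    ev_s(i) = ev_vm[i];
  }

  List snaps = List::create(
    _["time"] = snap_t.head(nsnap),
    _["energy"] = snap_energy.rows(0, nsnap > 0 ? nsnap - 1 : 0),
    _["deleted"] = snap_counts.rows(0, nsnap > 0 ? nsnap - 1 : 0),
    _["impactor"] = snap_imp.rows(0, nsnap > 0 ? nsnap - 1 : 0));
  if (record_fields) {
    snaps["vm"] = arma::mat(vm_hist.cols(0, nsnap > 0 ? nsnap - 1 : 0));
    snaps["dispmag"] = arma::mat(dispmag_hist.cols(0, nsnap > 0 ? nsnap - 1 : 0));
  }

  return List::create(
    _["time"] = t, _["n_steps"] = (double)step, _["dt"] = dt,
    _["disp"] = disp, _["vel"] = vel, _["acc"] = acc,
    _["stress"] = stress, _["active"] = active,
    _["impactor_center"] = impactor_center, _["impactor_vel"] = impactor_vel,
    _["impactor_active"] = impactor_active,
    _["t_touch"] = t_touch, _["t_sep"] = t_sep,
    _["event_elem"] = events, _["event_time"] = ev_t, _["event_vm"] = ev_s,
    _["snapshots"] = snaps);
}
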