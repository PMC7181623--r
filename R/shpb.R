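# One-dimensional stress-wave analysis for the split Hopkinson pressure bar
# (SHPB): specimen stress, strain and strain rate from the incident,
# reflected and transmitted bar strains,
#
#   sigma_s(t) = E (A_b / A_s) eps_T(t)
#   eps_s(t)   = -(2 C0 / l_s) integral_0^t eps_R dt
#   eps_dot(t) = -(2 C0 / l_s) eps_R(t)
#
# plus a forward generator of synthetic gauge records for
# elastic-perfectly-plastic specimens, used as a parameter-recovery oracle.
#
# Sign convention: compression positive internally. The incident and
# transmitted pulses are then positive and the reflected pulse negative
# (eps_R = eps_T - eps_I), which carries the minus signs of the strain and
# strain-rate formulas. Records measured with the opposite polarity can be
# declared `sign_convention = "tension_positive"` and are flipped on entry.

#' Pressure-bar properties
#'
#' @param E Young's modulus of the bars, Pa. Default: steel bars, 209 GPa.
#' @param rho bar density, kg/m^3. Default 7830.
#' @param area bar cross-sectional area `A_b`, m^2. Default: a 14.5 mm
#'   diameter bar.
#' @param C0 optional bar wave speed; if supplied it must equal
#'   `sqrt(E/rho)` to 1e-12 relative, otherwise it is derived.
#' @return object of class `oi_bar`, with the derived wave speed `C0`.
#' @export
bar_properties <- function(E = 209e9, rho = 7830,
                           area = pi * (0.0145 / 2)^2, C0 = NULL) {
  stopifnot(E > 0, rho > 0, area > 0)
  c0 <- sqrt(E / rho)
  if (!is.null(C0) && abs(C0 - c0) > 1e-12 * c0)
    stop("supplied C0 is inconsistent with sqrt(E/rho)")
  structure(list(E = E, rho = rho, area = area, C0 = c0), class = "oi_bar")
}

#' Specimen geometry
#'
#' @param length undeformed specimen length `l_s` along the loading axis, m.
#' @param area specimen cross-sectional area `A_s`, m^2.
#' @return object of class `oi_specimen`.
#' @export
specimen_geometry <- function(length, area) {
  stopifnot(length > 0, area > 0)
  structure(list(length = length, area = area), class = "oi_specimen")
}

#' Elastic-perfectly-plastic specimen material for the wave generator
#'
#' @param modulus specimen Young's modulus, Pa.
#' @param yield_strength yield stress, Pa; stress is capped at this value
#'   with no hardening.
#' @return object of class `oi_epp_material`.
#' @export
epp_material <- function(modulus, yield_strength) {
  stopifnot(modulus > 0, yield_strength > 0)
  structure(list(modulus = modulus, yield_strength = yield_strength),
            class = "oi_epp_material")
}

#' Bundle SHPB gauge channels into a record
#'
#' @param time uniformly sampled instants, s (strictly increasing).
#' @param incident,reflected,transmitted dimensionless bar strains.
#' @param sign_convention `"compression_positive"` (internal convention) or
#'   `"tension_positive"`; tension-positive data are negated on entry so all
#'   downstream analysis sees compression-positive strains.
#' @return object of class `oi_gauge_record`.
#' @export
gauge_record <- function(time, incident, reflected, transmitted,
                         sign_convention = c("compression_positive",
                                             "tension_positive")) {
  sign_convention <- match.arg(sign_convention)
  n <- length(time)
  if (length(incident) != n || length(reflected) != n ||
      length(transmitted) != n)
    stop("all channels must have the same length as time")
  dt <- diff(time)
  if (n < 2 || any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("non-uniform time grid: analysis requires uniform sampling")
  s <- if (sign_convention == "tension_positive") -1 else 1
  structure(list(time = as.numeric(time), incident = s * as.numeric(incident),
                 reflected = s * as.numeric(reflected),
                 transmitted = s * as.numeric(transmitted),
                 sign_convention = "compression_positive"),
            class = "oi_gauge_record")
}

#' Specimen stress from the transmitted wave
#'
#' `sigma_s(t) = E (A_b/A_s) eps_T(t)`, pointwise.
#'
#' @param record an [gauge_record()].
#' @param bar an [bar_properties()].
#' @param spec a [specimen_geometry()].
#' @return stress series in Pa (compression positive).
#' @export
specimen_stress <- function(record, bar, spec) {
  stopifnot(inherits(record, "oi_gauge_record"), inherits(bar, "oi_bar"),
            inherits(spec, "oi_specimen"))
  if (is.null(record$transmitted)) stop("missing transmitted channel")
  bar$E * (bar$area / spec$area) * record$transmitted
}

#' Specimen strain from the reflected wave
#'
#' `eps_s(t) = -(2 C0 / l_s) int_0^t eps_R dtau`, by cumulative trapezoidal
#' integration on the record's uniform grid; `eps_s(0) = 0`.
#'
#' @inheritParams specimen_stress
#' @return dimensionless strain series (compression positive).
#' @export
specimen_strain <- function(record, bar, spec) {
  stopifnot(inherits(record, "oi_gauge_record"), inherits(bar, "oi_bar"),
            inherits(spec, "oi_specimen"))
  -(2 * bar$C0 / spec$length) *
    as.numeric(pracma::cumtrapz(record$time, record$reflected))
}

#' Specimen strain rate from the reflected wave
#'
#' `eps_dot(t) = -(2 C0 / l_s) eps_R(t)`, pointwise. Its cumulative
#' trapezoidal integral reproduces [specimen_strain()] exactly on the shared
#' discretization.
#'
#' @inheritParams specimen_stress
#' @return strain-rate series in 1/s.
#' @export
specimen_strain_rate <- function(record, bar, spec) {
  stopifnot(inherits(record, "oi_gauge_record"), inherits(bar, "oi_bar"),
            inherits(spec, "oi_specimen"))
  -(2 * bar$C0 / spec$length) * record$reflected
}

#' Reconstruct the specimen stress-strain curve from a gauge record
#'
#' Bundles the stress, strain and strain-rate histories on the common time
#' grid and reports the force-equilibrium residual series
#' `eps_I + eps_R - eps_T` (zero when the specimen is in perfect one-wave /
#' two-wave equilibrium) as a diagnostic.
#'
#' @inheritParams specimen_stress
#' @return object of class `oi_ss_curve` with fields `time`, `strain`,
#'   `stress`, `strain_rate`, `equilibrium_residual`.
#' @export
reconstruct_curve <- function(record, bar, spec) {
  curve <- list(time = record$time,
                strain = specimen_strain(record, bar, spec),
                stress = specimen_stress(record, bar, spec),
                strain_rate = specimen_strain_rate(record, bar, spec),
                equilibrium_residual = record$incident + record$reflected -
                  record$transmitted)
  structure(curve, class = "oi_ss_curve")
}

#' Extract the dynamic yield strength from a stress-strain curve
#'
#' `method = "plateau"` (default, matching elastic-perfectly-plastic
#' response): the initial modulus is fitted to the early loading branch and
#' the yield stress is the mean stress over the post-linear plateau, defined
#' as the loading samples whose tangent modulus has dropped below 10% of the
#' initial modulus. `method = "offset"` returns the stress at the 0.2%
#' plastic-strain offset intersection. A fully linear curve gives an explicit
#' no-yield result (`detected = FALSE`), not an error.
#'
#' @param curve an [reconstruct_curve()] result.
#' @param method `"plateau"` or `"offset"`.
#' @param tangent_fraction plateau threshold as a fraction of the initial
#'   modulus (default 0.1).
#' @param offset plastic-strain offset for the offset method (default 0.002).
#' @return object of class `oi_yield`: list with `yield` (Pa, `NA` if not
#'   detected), `detected`, `initial_modulus`, `method`.
#' @export
extract_yield_strength <- function(curve, method = c("plateau", "offset"),
                                   tangent_fraction = 0.1, offset = 0.002) {
  stopifnot(inherits(curve, "oi_ss_curve"))
  method <- match.arg(method)
  # loading portion: up to peak strain
  imax <- which.max(curve$strain)
  eps <- curve$strain[seq_len(imax)]
  sig <- curve$stress[seq_len(imax)]
  live <- which(eps > 1e-12 * max(eps, 1e-300))
  no_yield <- structure(list(yield = NA_real_, detected = FALSE,
                             initial_modulus = NA_real_, method = method),
                        class = "oi_yield")
  if (length(live) < 5) return(no_yield)
  eps <- eps[live]; sig <- sig[live]
  # initial modulus from the early loading branch (origin-constrained fit)
  early <- which(eps <= 0.2 * max(eps) & sig > 0)
  if (length(early) < 3) early <- seq_len(min(5, length(eps)))
  E0 <- sum(sig[early] * eps[early]) / sum(eps[early]^2)
  if (!is.finite(E0) || E0 <= 0) return(no_yield)

  if (method == "offset") {
    g <- sig - E0 * (eps - offset)
    cross <- which(g[-1] <= 0 & g[-length(g)] > 0)
    if (!length(cross)) return(no_yield)
    i <- cross[1]
    w <- g[i] / (g[i] - g[i + 1])
    y <- sig[i] + w * (sig[i + 1] - sig[i])
    return(structure(list(yield = y, detected = TRUE, initial_modulus = E0,
                          method = method), class = "oi_yield"))
  }

  n <- length(eps)
  tangent <- rep(NA_real_, n)
  de <- eps[3:n] - eps[1:(n - 2)]
  ok <- de > 0
  tangent[2:(n - 1)][ok] <- (sig[3:n] - sig[1:(n - 2)])[ok] / de[ok]
  plateau <- which(is.finite(tangent) & tangent < tangent_fraction * E0 &
                   sig > 0.5 * max(sig))
  if (!length(plateau)) return(no_yield)
  structure(list(yield = mean(sig[plateau]), detected = TRUE,
                 initial_modulus = E0, method = method,
                 plateau_index = plateau), class = "oi_yield")
}

#' Synthesize SHPB gauge records for an elastic-perfectly-plastic specimen
#'
#' Forward model used as the parameter-recovery oracle for the wave
#' analysis. The incident pulse is a trapezoid of amplitude
#' `eps_I = v / (2 C0)` and duration `2 L_striker / C0` with 10% rise and
#' fall. The specimen is treated as in quasi-static force equilibrium (the
#' standard SHPB assumption): at each sample the transmitted strain solves
#' `sigma(eps_s) A_s = E A_b eps_T`, with the specimen strain advanced
#' trapezoidally by `eps_dot = (2 C0 / l_s)(eps_I - eps_T)` and the implicit
#' equation fixed-point iterated to 1e-10. The reflected wave is then
#' `eps_R = eps_T - eps_I` (compression positive).
#'
#' @param material an [epp_material()].
#' @param spec a [specimen_geometry()].
#' @param bar an [bar_properties()].
#' @param striker_velocity striker impact speed, m/s (> 0 for a pulse; 0
#'   gives an all-zero record).
#' @param striker_length striker bar length, m; sets the pulse duration.
#' @param dt sample interval, s; must resolve the pulse with at least 200
#'   samples.
#' @param t_total total record length, s (default 1.3 pulse durations).
#' @return an [gauge_record()], compression positive.
#' @export
synthesize_waves <- function(material, spec, bar, striker_velocity,
                             striker_length = 0.3, dt = 2e-7,
                             t_total = NULL) {
  stopifnot(inherits(material, "oi_epp_material"),
            inherits(spec, "oi_specimen"), inherits(bar, "oi_bar"),
            striker_velocity >= 0, striker_length > 0, dt > 0)
  C0 <- bar$C0
  dur <- 2 * striker_length / C0
  if (dur / dt < 200)
    stop("dt does not resolve the pulse: need >= 200 samples, got ",
         round(dur / dt))
  if (is.null(t_total)) t_total <- 1.3 * dur
  time <- seq(0, t_total, by = dt)
  amp <- striker_velocity / (2 * C0)
  rise <- 0.1 * dur
  eps_i <- pmin(pmax(time / rise, 0), 1) - pmin(pmax((time - dur + rise) / rise, 0), 1)
  eps_i <- amp * pmax(eps_i, 0)

  n <- length(time)
  eps_t <- numeric(n)
  eps_s <- 0      # specimen strain (compression positive)
  eps_p <- 0      # plastic strain
  rate_coef <- 2 * C0 / spec$length
  trans_coef <- spec$area / (bar$E * bar$area)
  epp_stress <- function(e, ep) {
    trial <- material$modulus * (e - ep)
    max(min(trial, material$yield_strength), -material$yield_strength)
  }
  rate_prev <- rate_coef * (eps_i[1] - 0)   # eps_t[1] solved below if needed
  # sample 1: at t = 0 the pulse is zero, so the specimen is unstrained
  for (k in 2:n) {
    et <- eps_t[k - 1]
    for (it in 1:200) {
      e_new <- eps_s + (dt / 2) * (rate_prev + rate_coef * (eps_i[k] - et))
      sig <- epp_stress(e_new, eps_p)
      et_new <- sig * trans_coef
      if (abs(et_new - et) <= 1e-10) { et <- et_new; break }
      et <- et_new
      if (it == 200) stop("transmitted-wave fixed point failed to converge ",
                          "at t = ", time[k])
    }
    e_new <- eps_s + (dt / 2) * (rate_prev + rate_coef * (eps_i[k] - et))
    sig <- epp_stress(e_new, eps_p)
    if (abs(material$modulus * (e_new - eps_p)) > material$yield_strength)
      eps_p <- e_new - sig / material$modulus
    eps_s <- e_new
    eps_t[k] <- et
    rate_prev <- rate_coef * (eps_i[k] - et)
  }
  gauge_record(time, incident = eps_i, reflected = eps_t - eps_i,
               transmitted = eps_t)
}

#' Read / write SHPB gauge records as CSV
#'
#' Columns: `time_s, incident, reflected, transmitted`.
#'
#' @param path CSV file path.
#' @param sign_convention polarity of the stored data (see
#'   [gauge_record()]).
#' @return a `oi_gauge_record` (read) or `path` invisibly (write).
#' @export
read_gauge_csv <- function(path, sign_convention = "compression_positive") {
  d <- read.csv(path)
  need <- c("time_s", "incident", "reflected", "transmitted")
  if (!all(need %in% names(d)))
    stop("gauge CSV must have columns: ", paste(need, collapse = ", "))
  gauge_record(d$time_s, d$incident, d$reflected, d$transmitted,
               sign_convention = sign_convention)
}

#' @rdname read_gauge_csv
#' @param record a `oi_gauge_record` to write.
#' @export
write_gauge_csv <- function(record, path) {
  write.csv(data.frame(time_s = record$time, incident = record$incident,
                       reflected = record$reflected,
                       transmitted = record$transmitted),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a reconstructed stress-strain curve as CSV
#'
#' Columns: `strain, stress_Pa, strain_rate_per_s`.
#' @param curve an `oi_ss_curve`.
#' @param path CSV file path.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(data.frame(strain = curve$strain, stress_Pa = curve$stress,
                       strain_rate_per_s = curve$strain_rate),
            path, row.names = FALSE)
  invisible(path)
}
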