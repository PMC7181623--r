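# Per-region isotropic elastic constants, densities, and dynamic yield
# strengths. Yield defaults are the dynamic (SHPB) test results for rabbit
# femur: 180 MPa cortical, 8.9 MPa cancellous. The elastic constants default
# to literature-typical values and are flagged "assumed"; all are
# overridable from a YAML config.

#' Isotropic linear-elastic material
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio, dimensionless, in (-1, 0.5).
#' @param rho mass density, kg/m^3.
#' @param assumed logical flag: `TRUE` marks a literature-typical default
#'   rather than a measured value.
#' @return object of class `oi_elastic_material`.
#' @export
elastic_material <- function(E, nu, rho, assumed = FALSE) {
  bad <- character()
  if (!is.finite(E) || E <= 0) bad <- c(bad, "E must be > 0")
  if (!is.finite(nu) || nu <= -1 || nu >= 0.5)
    bad <- c(bad, "nu must be in (-1, 0.5)")
  if (!is.finite(rho) || rho <= 0) bad <- c(bad, "rho must be > 0")
  if (length(bad)) stop("invalid material: ", paste(bad, collapse = "; "))
  structure(list(E = E, nu = nu, rho = rho, assumed = isTRUE(assumed)),
            class = "oi_elastic_material")
}

#' Failure parameters (von Mises yield) for a set of regions
#'
#' @param yield_strength dynamic yield strength, Pa.
#' @param applies_to character vector of region labels. The implant is never
#'   given failure parameters by default (titanium does not fail at bone
#'   stress levels and the damage rule targets bone).
#' @return object of class `oi_failure_params`.
#' @export
failure_params <- function(yield_strength, applies_to) {
  if (!is.finite(yield_strength) || yield_strength <= 0)
    stop("invalid failure params: yield_strength must be > 0")
  structure(list(yield_strength = yield_strength, applies_to = applies_to),
            class = "oi_failure_params")
}

#' Material library mapping regions to materials and failure rules
#'
#' @param cortical,cancellous,implant `oi_elastic_material` objects.
#' @param cortical_yield,cancellous_yield yield strengths in Pa; bone regions
#'   must carry failure parameters.
#' @return object of class `oi_material_library`.
#' @export
material_library <- function(cortical, cancellous, implant,
                             cortical_yield, cancellous_yield) {
  for (m in list(cortical, cancellous, implant))
    stopifnot(inherits(m, "oi_elastic_material"))
  structure(list(
    IMPLANT = list(elastic = implant, failure = NULL),
    CORTICAL = list(elastic = cortical,
                    failure = failure_params(cortical_yield, "CORTICAL")),
    CANCELLOUS = list(elastic = cancellous,
                      failure = failure_params(cancellous_yield, "CANCELLOUS"))),
    class = "oi_material_library")
}

#' Default material library
#'
#' Dynamic yield strengths are the SHPB test results for rabbit femur
#' (cortical 180 MPa, cancellous 8.9 MPa). Elastic constants are
#' literature-typical values for cortical bone, cancellous bone as an
#' effective continuum, and commercially pure titanium, flagged `assumed`.
#'
#' @return an `oi_material_library`.
#' @export
default_material_library <- function() {
  material_library(
    cortical = elastic_material(E = 15e9, nu = 0.3, rho = 1900, assumed = TRUE),
    cancellous = elastic_material(E = 0.5e9, nu = 0.3, rho = 500, assumed = TRUE),
    implant = elastic_material(E = 110e9, nu = 0.33, rho = 4500, assumed = TRUE),
    cortical_yield = 180e6,
    cancellous_yield = 8.9e6)
}

#' Load a material library from a YAML config
#'
#' The file may override any subset of the defaults; missing entries keep
#' their default values. Expected structure (units in the key names):
#' ```
#' cortical:   {E_Pa: 1.5e10, nu: 0.3, rho_kg_m3: 1900, yield_Pa: 1.8e8}
#' cancellous: {E_Pa: 5.0e8,  nu: 0.3, rho_kg_m3: 500,  yield_Pa: 8.9e6}
#' implant:    {E_Pa: 1.1e11, nu: 0.33, rho_kg_m3: 4500}
#' ```
#'
#' @param path path to a YAML file, or `NULL` for the full default library.
#' @return an `oi_material_library`.
#' @export
load_material_config <- function(path = NULL) {
  lib <- default_material_library()
  if (is.null(path)) return(lib)
  if (!file.exists(path)) stop("material config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(lib)
  known <- c("cortical", "cancellous", "implant")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown material region(s): ",
                          paste(extra, collapse = ", "))
  out <- lapply(known, function(rg) {
    cur <- lib[[toupper(rg)]]
    o <- cfg[[rg]]
    if (is.null(o)) return(cur)
    el <- cur$elastic
    el2 <- elastic_material(
      E = if (!is.null(o$E_Pa)) as.numeric(o$E_Pa) else el$E,
      nu = if (!is.null(o$nu)) as.numeric(o$nu) else el$nu,
      rho = if (!is.null(o$rho_kg_m3)) as.numeric(o$rho_kg_m3) else el$rho,
      assumed = is.null(o$E_Pa) && el$assumed)
    fail <- cur$failure
    if (!is.null(o$yield_Pa))
      fail <- failure_params(as.numeric(o$yield_Pa), toupper(rg))
    list(elastic = el2, failure = fail)
  })
  names(out) <- toupper(known)
  structure(out, class = "oi_material_library")
}

#' Lame parameters of an isotropic material
#'
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))`, `mu = E / (2 (1 + nu))`.
#'
#' @param m an `oi_elastic_material`.
#' @return named numeric vector `c(lambda = , mu = )`, Pa.
#' @export
lame_parameters <- function(m) {
  stopifnot(inherits(m, "oi_elastic_material"))
  if (m$nu > 0.5 - 1e-9)
    stop("nu at the incompressible limit is not supported")
  c(lambda = m$E * m$nu / ((1 + m$nu) * (1 - 2 * m$nu)),
    mu = m$E / (2 * (1 + m$nu)))
}

#' Dilatational (P-) wave speed of a material
#'
#' `c_d = sqrt((lambda + 2 mu) / rho)`; at `nu = 0` this reduces to the 1-D
#' bar speed `sqrt(E / rho)`. Used for the explicit-dynamics CFL limit.
#'
#' @param m an `oi_elastic_material`.
#' @return wave speed in m/s.
#' @export
dilatational_wave_speed <- function(m) {
  lm <- lame_parameters(m)
  sqrt((lm["lambda"] + 2 * lm["mu"]) / m$rho)[[1]]
}

#' @export
print.oi_material_library <- function(x, ...) {
  cat("material library (region: E GPa, nu, rho kg/m3, yield MPa)\n")
  for (rg in names(x)) {
    e <- x[[rg]]$elastic
    y <- if (is.null(x[[rg]]$failure)) "-" else
      sprintf("%.3g", x[[rg]]$failure$yield_strength / 1e6)
    cat(sprintf("  %-10s %7.3g %5.2f %6.0f %8s%s\n", rg, e$E / 1e9, e$nu,
                e$rho, y, if (e$assumed) "  [assumed]" else ""))
  }
  invisible(x)
}

# JSON-ready echo of a material library for run reports
material_library_echo <- function(lib) {
  lapply(lib, function(r) {
    out <- list(E_Pa = r$elastic$E, nu = r$elastic$nu,
                rho_kg_m3 = r$elastic$rho, assumed = r$elastic$assumed)
    if (!is.null(r$failure)) out$yield_Pa <- r$failure$yield_strength
    out
  })
}
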