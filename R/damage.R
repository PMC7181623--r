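# von Mises yield / element-deletion failure rule: bone elements whose von
# Mises stress reaches their region's dynamic yield strength are declared
# ineffective and deleted (stiffness removed, mass retained). The implant is
# exempt. "Reached" is interpreted as >=, so ties at exactly the yield
# strength break toward deletion.

#' von Mises equivalent stress
#'
#' `sqrt(1/2 [(s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2] + 3 (s12^2 + s23^2 +
#' s31^2))`; invariant under rigid rotation of the stress field.
#'
#' @param sigma a 3 x 3 symmetric stress tensor, a length-6 Voigt vector
#'   `[11, 22, 33, 12, 23, 31]`, or an E x 6 matrix of Voigt rows.
#' @return scalar (or vector, for a Voigt matrix) equivalent stress, Pa.
#' @export
von_mises <- function(sigma) {
  if (is.matrix(sigma) && nrow(sigma) == 3 && ncol(sigma) == 3) {
    if (max(abs(sigma - t(sigma))) > 1e-8 * max(abs(sigma), 1e-300))
      stop("stress tensor must be symmetric")
    sigma <- matrix(c(sigma[1, 1], sigma[2, 2], sigma[3, 3],
                      sigma[1, 2], sigma[2, 3], sigma[3, 1]), 1, 6)
  } else if (!is.matrix(sigma)) {
    if (length(sigma) != 6) stop("expected a 3x3 tensor or length-6 Voigt vector")
    sigma <- matrix(sigma, 1, 6)
  }
  if (any(!is.finite(sigma))) stop("non-finite stress entries")
  v <- sqrt(0.5 * ((sigma[, 1] - sigma[, 2])^2 + (sigma[, 2] - sigma[, 3])^2 +
                   (sigma[, 3] - sigma[, 1])^2) +
            3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2))
  if (length(v) == 1) v[[1]] else v
}

#' Apply the yield / element-deletion failure rule to a state
#'
#' Every active element with finite yield strength (bone regions; the implant
#' carries none) whose von Mises stress has reached its region's yield is
#' deactivated: its stiffness is removed for all subsequent steps, its mass
#' is retained, and its reported stress becomes zero. Deletion is
#' irreversible. Events are logged with deletion time and stress.
#'
#' @param state an `oi_sim_state` with current stresses.
#' @param model the [fe_model()] supplying per-element yield strengths.
#' @return list with the updated `state` and an `events` data frame
#'   (element, region, time_s, vm_Pa).
#' @export
apply_failure <- function(state, model) {
  stopifnot(inherits(state, "oi_sim_state"), inherits(model, "oi_fe_model"))
  vm <- von_mises(state$stress)
  if (length(vm) == 1) vm <- rep(vm, 1)
  hit <- which(state$active & is.finite(model$yield) & vm >= model$yield)
  events <- data.frame(element = hit,
                       region = model$mesh$region[hit],
                       time_s = rep(state$time, length(hit)),
                       vm_Pa = vm[hit])
  if (length(hit)) {
    state$active[hit] <- FALSE
    state$stress[hit, ] <- 0
  }
  list(state = state, events = events)
}

#' Tally damage events into a per-region report
#'
#' Counts ineffective (deleted) elements by region and, as a separate view
#' (not a third region), those lying at the bone-implant interface. The
#' interface membership defaults to the mesh's `INTERFACE` element set (bone
#' elements within one grid spacing of the implant surface) and can be
#' overridden with any element-index vector.
#'
#' @param events a data frame of damage events (element, region, time_s,
#'   vm_Pa), e.g. from [fem_run()] or [apply_failure()].
#' @param mesh the `oi_mesh` the events refer to.
#' @param interface element indices counted as interface (default
#'   `mesh$element_sets$INTERFACE`).
#' @return object of class `oi_damage_report`: list with `counts` (named:
#'   total, cortical, cancellous, interface), `by_region`, `events`.
#' @export
tally_damage <- function(events, mesh, interface = NULL) {
  stopifnot(inherits(mesh, "oi_mesh"))
  if (nrow(events) && any(events$element < 1 | events$element > nrow(mesh$tets)))
    stop("event references an unknown element")
  if (is.null(interface)) interface <- mesh$element_sets$INTERFACE
  by_region <- c(CORTICAL = sum(events$region == "CORTICAL"),
                 CANCELLOUS = sum(events$region == "CANCELLOUS"))
  counts <- c(total = nrow(events),
              cortical = by_region[["CORTICAL"]],
              cancellous = by_region[["CANCELLOUS"]],
              interface = sum(events$element %in% interface))
  structure(list(counts = counts, by_region = by_region, events = events),
            class = "oi_damage_report")
}

#' @export
print.oi_damage_report <- function(x, ...) {
  cat("damage report (ineffective elements):\n")
  cat(sprintf("  total %d | cortical %d | cancellous %d | interface %d\n",
              x$counts["total"], x$counts["cortical"], x$counts["cancellous"],
              x$counts["interface"]))
  invisible(x)
}

#' Write damage events as CSV
#'
#' Columns: `element, region, time_s, vm_Pa`.
#' @param report an `oi_damage_report` (or a raw events data frame).
#' @param path CSV file path.
#' @export
write_damage_csv <- function(report, path) {
  ev <- if (inherits(report, "oi_damage_report")) report$events else report
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
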