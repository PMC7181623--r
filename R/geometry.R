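# Parametric conformal tetrahedral mesh of a cylindrical implant embedded
# through a cortical shell into cancellous bone. A structured hexahedral grid
# is split into 6 tets per cell (Kuhn subdivision along a shared diagonal),
# which is conformal by construction, so the bone-implant "tie constraint"
# is realized as shared nodes at the interface.

#' Geometry parameters for the implant-in-bone block
#'
#' All lengths are in meters (SI). The implant is a smooth cylinder of the
#' given radius and length, centered on the block's transverse midpoint and
#' entering from one block face along a coordinate axis. A cortical shell of
#' the given thickness lines the outer block surface; the remainder is
#' cancellous bone.
#'
#' @param block_dims length-3 numeric, block extents in m.
#' @param grid_spacing structured grid spacing in m; must not exceed
#'   `cortical_thickness` so the shell is resolvable, and must divide the
#'   block extents.
#' @param implant_radius implant radius in m (default 2 mm, i.e. a 4 mm
#'   diameter fixture).
#' @param implant_length implant length in m (default 8 mm).
#' @param cortical_thickness cortical shell thickness in m (default 1.5 mm).
#' @param implant_axis one of `"x"`, `"y"`, `"z"`: the coordinate axis of the
#'   implant's long axis (default `"z"`).
#' @param implant_entry_face `"+"` or `"-"`: which face of that axis the
#'   implant enters from (default `"+"`, the top face).
#' @param trabecular_porosity fraction in `[0, 1)` of cancellous elements to
#'   be knocked out as a stochastic stand-in for unresolved trabecular
#'   microstructure; default 0 (homogeneous effective continuum).
#' @param random_seed integer seed used only by the porosity knockout.
#' @param thread_amplitude optional radius modulation amplitude in m
#'   (annular ridges standing in for implant threads, whose true geometry is
#'   not dimensioned); default 0, a smooth cylinder.
#' @param thread_pitch axial period of the radius modulation, m.
#' @return an object of class `oi_geometry_params`.
#' @export
geometry_params <- function(block_dims = c(0.012, 0.012, 0.016),
                            grid_spacing = 0.001,
                            implant_radius = 0.002,
                            implant_length = 0.008,
                            cortical_thickness = 0.0015,
                            implant_axis = "z",
                            implant_entry_face = "+",
                            trabecular_porosity = 0,
                            random_seed = 1L,
                            thread_amplitude = 0,
                            thread_pitch = 0.001) {
  stopifnot(length(block_dims) == 3, all(block_dims > 0),
            grid_spacing > 0, implant_radius > 0, implant_length > 0,
            cortical_thickness > 0)
  implant_axis <- match.arg(implant_axis, c("x", "y", "z"))
  implant_entry_face <- match.arg(implant_entry_face, c("+", "-"))
  if (trabecular_porosity < 0 || trabecular_porosity >= 1)
    stop("trabecular_porosity must be in [0, 1)")
  ax <- match(implant_axis, c("x", "y", "z"))
  if (implant_length + cortical_thickness >= block_dims[ax])
    stop("implant_length + cortical_thickness must be smaller than the ",
         "block extent along the implant axis")
  if (any(2 * implant_radius >= block_dims[-ax]))
    stop("implant diameter must be smaller than the transverse block extents")
  if (grid_spacing > cortical_thickness + 1e-12)
    stop("resolution error: grid_spacing exceeds cortical_thickness; ",
         "the cortical shell would not contain a full element layer")
  if (thread_amplitude < 0 || thread_amplitude >= implant_radius)
    stop("thread_amplitude must be in [0, implant_radius)")
  if (thread_pitch <= 0) stop("thread_pitch must be > 0")
  ncell <- block_dims / grid_spacing
  if (any(abs(ncell - round(ncell)) > 1e-6))
    stop("grid_spacing must divide every block extent")
  structure(list(block_dims = block_dims, grid_spacing = grid_spacing,
                 implant_radius = implant_radius,
                 implant_length = implant_length,
                 cortical_thickness = cortical_thickness,
                 implant_axis = implant_axis,
                 implant_entry_face = implant_entry_face,
                 trabecular_porosity = trabecular_porosity,
                 random_seed = as.integer(random_seed),
                 thread_amplitude = thread_amplitude,
                 thread_pitch = thread_pitch),
            class = "oi_geometry_params")
}

# Kuhn subdivision of the unit cell: 6 tets along the 0-7 diagonal, one per
# monotone lattice path; corner indices use binary encoding bit1=x bit2=y
# bit3=z (1-based corners 1..8).
.kuhn_patterns <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  bits <- c(1L, 2L, 4L)
  pats <- t(vapply(perms, function(p) {
    a <- bits[p[1]]
    b <- a + bits[p[2]]
    c(0L, a, b, 7L) + 1L
  }, integer(4)))
  # reorder for positive signed volume on the unit cell
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  for (i in seq_len(nrow(pats))) {
    p <- corners[pats[i, ], ]
    v <- det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))
    if (v < 0) pats[i, c(3, 4)] <- pats[i, c(4, 3)]
  }
  pats
}

#' Build the implant-in-bone tetrahedral mesh
#'
#' Generates a structured grid of hexahedral cells over the block, splits
#' each into 6 tetrahedra sharing the cell diagonal (conformal by
#' construction), and labels elements by a centroid predicate: inside the
#' implant cylinder and within `implant_length` of the entry face ->
#' `IMPLANT`; within `cortical_thickness` of the outer block surface ->
#' `CORTICAL`; otherwise `CANCELLOUS`. Node sets `FIXED` (two block faces
#' transverse to the implant axis) and `IMPLANT_TOP` (entry-face nodes of the
#' implant) are populated, along with per-region element sets and an
#' `INTERFACE` element set (bone elements within one grid spacing of the
#' implant surface).
#'
#' @param params an [geometry_params()] object.
#' @return an object of class `oi_mesh` with fields `coords` (N x 3 m),
#'   `tets` (E x 4, 1-based node indices, positive signed volume),
#'   `region` (character per element), `node_sets`, `element_sets`,
#'   `centroids`, and the originating `params`.
#' @export
build_mesh <- function(params) {
  stopifnot(inherits(params, "oi_geometry_params"))
  h <- params$grid_spacing
  nc <- as.integer(round(params$block_dims / h))
  nx <- nc[1]; ny <- nc[2]; nz <- nc[3]
  npx <- nx + 1L; npy <- ny + 1L; npz <- nz + 1L

  gx <- seq(0, by = h, length.out = npx)
  gy <- seq(0, by = h, length.out = npy)
  gz <- seq(0, by = h, length.out = npz)
  coords <- cbind(rep(gx, times = npy * npz),
                  rep(rep(gy, each = npx), times = npz),
                  rep(gz, each = npx * npy))

  node_id <- function(i, j, k) 1L + i + npx * (j + npy * k)  # i,j,k 0-based
  ci <- rep(0:(nx - 1L), times = ny * nz)
  cj <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  ck <- rep(0:(nz - 1L), each = nx * ny)
  # 8 corners per cell, binary order (x fastest)
  corner_off <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))
  cell_nodes <- matrix(0L, length(ci), 8)
  for (c8 in 1:8)
    cell_nodes[, c8] <- node_id(ci + corner_off[c8, 1],
                                cj + corner_off[c8, 2],
                                ck + corner_off[c8, 3])
  pats <- .kuhn_patterns()
  tets <- do.call(rbind, lapply(seq_len(6), function(p) cell_nodes[, pats[p, ]]))
  storage.mode(tets) <- "integer"

  centroids <- (coords[tets[, 1], ] + coords[tets[, 2], ] +
                coords[tets[, 3], ] + coords[tets[, 4], ]) / 4

  ax <- match(params$implant_axis, c("x", "y", "z"))
  trans <- setdiff(1:3, ax)
  center <- params$block_dims / 2
  entry_coord <- if (params$implant_entry_face == "+") params$block_dims[ax] else 0
  depth <- if (params$implant_entry_face == "+")
    entry_coord - centroids[, ax] else centroids[, ax] - entry_coord
  rdist <- sqrt((centroids[, trans[1]] - center[trans[1]])^2 +
                (centroids[, trans[2]] - center[trans[2]])^2)
  r_eff <- params$implant_radius +
    params$thread_amplitude * sin(2 * pi * depth / params$thread_pitch)
  is_implant <- rdist <= r_eff &
    depth >= 0 & depth <= params$implant_length
  surf_dist <- pmin(centroids[, 1], params$block_dims[1] - centroids[, 1],
                    centroids[, 2], params$block_dims[2] - centroids[, 2],
                    centroids[, 3], params$block_dims[3] - centroids[, 3])
  is_cortical <- !is_implant & surf_dist <= params$cortical_thickness
  region <- ifelse(is_implant, "IMPLANT",
                   ifelse(is_cortical, "CORTICAL", "CANCELLOUS"))
  if (!any(region == "CORTICAL"))
    stop("resolution error: no element fits inside the cortical shell")

  # distance from bone element centroids to the implant cylinder surface
  dr <- rdist - params$implant_radius
  dz <- depth - params$implant_length   # > 0 below the implant tip
  d_side <- ifelse(depth >= 0 & depth <= params$implant_length, abs(dr), Inf)
  d_tip <- ifelse(dr <= 0, abs(dz),
                  sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2))
  d_cyl <- pmin(d_side, ifelse(dz >= 0, d_tip, Inf),
                sqrt(pmax(dr, 0)^2 + pmax(-depth, 0)^2))
  interface <- which(region != "IMPLANT" & d_cyl <= h)

  # entry-face nodes inside the implant footprint
  on_entry <- abs(coords[, ax] - entry_coord) < h / 2
  node_r <- sqrt((coords[, trans[1]] - center[trans[1]])^2 +
                 (coords[, trans[2]] - center[trans[2]])^2)
  implant_top <- which(on_entry & node_r <= params$implant_radius + 1e-9)

  mesh <- structure(list(
    coords = coords, tets = tets, region = region,
    centroids = centroids,
    node_sets = list(IMPLANT_TOP = implant_top),
    element_sets = list(IMPLANT = which(region == "IMPLANT"),
                        CORTICAL = which(region == "CORTICAL"),
                        CANCELLOUS = which(region == "CANCELLOUS"),
                        INTERFACE = interface),
    modulus_scale = rep(1, nrow(tets)),
    params = params), class = "oi_mesh")
  mesh$node_sets$FIXED <- select_fixed_nodes(mesh, c("x", "y", "z")[trans[1]])
  if (params$trabecular_porosity > 0)
    mesh <- apply_trabecular_porosity(mesh, params$trabecular_porosity,
                                      params$random_seed)
  mesh
}

#' Select the clamped nodes on a pair of opposite block faces
#'
#' The model is held by clamping both block faces normal to one coordinate
#' axis transverse to the implant (zero displacement in all three
#' directions). Clamping the faces normal to the implant axis itself is
#' rejected, since that would clamp the loaded face.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param face_pair `"x"`, `"y"` or `"z"`: the axis whose two faces are
#'   clamped.
#' @return integer vector of 1-based node indices.
#' @export
select_fixed_nodes <- function(mesh, face_pair) {
  stopifnot(inherits(mesh, "oi_mesh"))
  face_pair <- match.arg(face_pair, c("x", "y", "z"))
  if (face_pair == mesh$params$implant_axis)
    stop("face_pair must be transverse to the implant axis ",
         "(clamping the loaded face is not allowed)")
  ax <- match(face_pair, c("x", "y", "z"))
  h <- mesh$params$grid_spacing
  extent <- mesh$params$block_dims[ax]
  which(mesh$coords[, ax] < h / 2 | mesh$coords[, ax] > extent - h / 2)
}

#' Knock out a random fraction of cancellous elements
#'
#' A stochastic stand-in for trabecular microstructure that a continuum mesh
#' does not resolve: a uniformly random subset of `CANCELLOUS` elements of
#' the given fraction is removed (`mode = "remove"`) or has its modulus
#' scaled by 1e-6 (`mode = "soft"`). Deterministic under the seed; cortical
#' and implant elements are untouched. The caller's RNG state is preserved.
#'
#' @param mesh an `oi_mesh`.
#' @param fraction fraction in `[0, 1)` of cancellous elements to knock out.
#' @param seed integer seed (mandatory).
#' @param mode `"remove"` deletes the elements (orphaned nodes are purged and
#'   indices remapped); `"soft"` keeps them with negligible stiffness.
#' @return the modified `oi_mesh`.
#' @export
apply_trabecular_porosity <- function(mesh, fraction, seed,
                                      mode = c("remove", "soft")) {
  stopifnot(inherits(mesh, "oi_mesh"), fraction >= 0, fraction < 1)
  mode <- match.arg(mode)
  if (fraction == 0) return(mesh)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  canc <- mesh$element_sets$CANCELLOUS
  n_out <- round(fraction * length(canc))
  if (n_out == 0) return(mesh)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  out <- sort(sample(canc, n_out))

  if (mode == "soft") {
    mesh$modulus_scale[out] <- 1e-6
    mesh$element_sets$POROSITY <- out
    return(mesh)
  }

  keep <- setdiff(seq_len(nrow(mesh$tets)), out)
  # implant must remain attached to some bone
  imp_nodes <- unique(as.vector(mesh$tets[mesh$element_sets$IMPLANT, ]))
  bone_keep <- keep[mesh$region[keep] != "IMPLANT"]
  if (!any(mesh$tets[bone_keep, ] %in% imp_nodes))
    stop("porosity removal disconnects the implant from all bone")

  old_tets <- mesh$tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(old_tets)))
  remap <- integer(nrow(mesh$coords)); remap[used] <- seq_along(used)
  mesh$coords <- mesh$coords[used, , drop = FALSE]
  mesh$tets <- matrix(remap[old_tets], ncol = 4)
  storage.mode(mesh$tets) <- "integer"
  mesh$region <- mesh$region[keep]
  mesh$centroids <- mesh$centroids[keep, , drop = FALSE]
  mesh$modulus_scale <- mesh$modulus_scale[keep]
  elem_remap <- integer(length(mesh$region) + length(out))
  elem_remap[keep] <- seq_along(keep)
  mesh$element_sets <- lapply(mesh$element_sets, function(s) {
    s <- intersect(s, keep); elem_remap[s]
  })
  mesh$node_sets <- lapply(mesh$node_sets, function(s) {
    s <- intersect(s, used); remap[s]
  })
  mesh$porosity_removed <- out
  mesh
}

#' Signed tetrahedron volumes of a mesh
#' @param mesh an `oi_mesh`.
#' @return numeric vector of per-element volumes in m^3.
#' @export
tet_volumes <- function(mesh) {
  pre <- cpp_tet_precompute(mesh$coords, mesh$tets - 1L)
  pre$vol
}

#' Total mesh volume in m^3
#' @param mesh an `oi_mesh`.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

# Face-conformity audit: each interior face shared by exactly 2 tets,
# boundary faces by exactly 1. Returns the face-multiplicity table.
#' Check mesh conformity
#'
#' Counts how many tetrahedra share each triangular face. In a conformal
#' mesh every face occurs once (boundary) or twice (interior).
#'
#' @param mesh an `oi_mesh`.
#' @return named integer vector: counts of faces by multiplicity.
#' @export
face_multiplicity <- function(mesh) {
  tt <- mesh$tets
  faces <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)],
                 tt[, c(1, 3, 4)], tt[, c(2, 3, 4)])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  table(table(key))
}

#' @export
print.oi_mesh <- function(x, ...) {
  cat("implant-in-bone tetrahedral mesh\n")
  cat(sprintf("  nodes: %d, tets: %d (spacing %.3g mm)\n",
              nrow(x$coords), nrow(x$tets), x$params$grid_spacing * 1e3))
  tab <- table(x$region)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export a mesh as a legacy ASCII VTK unstructured grid
#'
#' Region labels (and any extra per-element scalars) are written as cell
#' data, so the file can be inspected in ParaView or read back by any VTK
#' reader.
#'
#' @param mesh an `oi_mesh`.
#' @param path output file path.
#' @param cell_data optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$coords); e <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "osseoimpact unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  write(t(mesh$coords), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", e, 5 * e), con)
  write(t(cbind(4L, mesh$tets - 1L)), con, ncolumns = 5)
  writeLines(sprintf("CELL_TYPES %d", e), con)
  write(rep(10L, e), con, ncolumns = 10)
  writeLines(sprintf("CELL_DATA %d", e), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  write(match(mesh$region, c("IMPLANT", "CORTICAL", "CANCELLOUS")) - 1L,
        con, ncolumns = 10)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    write(cell_data[[nm]], con, ncolumns = 6)
  }
  invisible(path)
}

#' Export a mesh in Abaqus-flavor .inp format
#'
#' Writes nodes, C3D4 elements and one element set per region, for
#' cross-checking the mesh in external solvers.
#'
#' @param mesh an `oi_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abaqus_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$coords)),
                     mesh$coords[, 1], mesh$coords[, 2], mesh$coords[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  for (rg in c("IMPLANT", "CORTICAL", "CANCELLOUS")) {
    writeLines(sprintf("*ELSET, ELSET=%s", rg), con)
    idx <- which(mesh$region == rg)
    if (length(idx))
      writeLines(paste(tapply(idx, ceiling(seq_along(idx) / 16),
                              paste, collapse = ", ")), con)
  }
  invisible(path)
}
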