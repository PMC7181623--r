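test_that("structured grid gives the analytic node and element counts", {
  m <- build_mesh(geometry_params(block_dims = c(0.012, 0.012, 0.016),
                                  grid_spacing = 0.001))
  expect_equal(nrow(m$coords), 13 * 13 * 17)
  expect_equal(nrow(m$tets), 12 * 12 * 16 * 6)
})

test_that("every tetrahedron has positive signed volume and the volumes sum to the block volume", {
  m <- build_mesh(tiny_geometry())
  v <- tet_volumes(m)
  expect_true(all(v > 0))
  block <- prod(m$params$block_dims)
  expect_lt(abs(sum(v) - block) / block, 1e-9)
})

test_that("region labels follow the centroid predicates", {
  p <- geometry_params(block_dims = c(0.012, 0.012, 0.016),
                       grid_spacing = 0.0005, cortical_thickness = 0.0015)
  m <- build_mesh(p)
  ax <- 3; ctr <- p$block_dims / 2
  rdist <- sqrt((m$centroids[, 1] - ctr[1])^2 + (m$centroids[, 2] - ctr[2])^2)
  depth <- p$block_dims[3] - m$centroids[, 3]
  imp <- m$region == "IMPLANT"
  expect_true(all(rdist[imp] <= p$implant_radius))
  expect_true(all(depth[imp] <= p$implant_length))
  surf <- pmin(m$centroids[, 1], p$block_dims[1] - m$centroids[, 1],
               m$centroids[, 2], p$block_dims[2] - m$centroids[, 2],
               m$centroids[, 3], p$block_dims[3] - m$centroids[, 3])
  expect_true(all(m$region[!imp & surf <= p$cortical_thickness] == "CORTICAL"))
  expect_true(all(m$region[surf > p$cortical_thickness & !imp] == "CANCELLOUS"))
  # regions partition the elements
  expect_equal(unname(sort(unlist(m$element_sets[c("IMPLANT", "CORTICAL",
                                                   "CANCELLOUS")]))),
               seq_len(nrow(m$tets)))
})

test_that("mesh is conformal: interior faces shared by exactly 2 tets, boundary by 1", {
  m <- build_mesh(tiny_geometry())
  mult <- face_multiplicity(m)
  expect_true(all(names(mult) %in% c("1", "2")))
  # boundary face count is analytic for a box grid: 2 triangles per exposed
  # cell face
  nc <- round(m$params$block_dims / m$params$grid_spacing)
  n_bnd <- 4 * (nc[1] * nc[2] + nc[2] * nc[3] + nc[1] * nc[3])
  expect_equal(unname(mult[["1"]]), n_bnd)
})

test_that("every node is referenced by at least one element", {
  m <- build_mesh(tiny_geometry())
  expect_setequal(unique(as.vector(m$tets)), seq_len(nrow(m$coords)))
})

test_that("doubling cortical thickness strictly increases cortical volume", {
  m1 <- build_mesh(tiny_geometry(cortical_thickness = 0.001))
  m2 <- build_mesh(tiny_geometry(cortical_thickness = 0.002))
  v1 <- sum(tet_volumes(m1)[m1$region == "CORTICAL"])
  v2 <- sum(tet_volumes(m2)[m2$region == "CORTICAL"])
  expect_gt(v2, v1)
})

test_that("implant element set is edge-connected", {
  m <- build_mesh(tiny_geometry())
  imp <- m$element_sets$IMPLANT
  # grow a connected component from the first implant element via shared nodes
  nodes_of <- function(e) as.vector(m$tets[e, ])
  comp <- imp[1]
  repeat {
    front_nodes <- unique(as.vector(m$tets[comp, ]))
    grown <- imp[apply(matrix(m$tets[imp, ] %in% front_nodes,
                              ncol = 4), 1, any)]
    if (length(grown) == length(comp)) break
    comp <- grown
  }
  expect_setequal(comp, imp)
})

test_that("fixed-node selection returns both transverse faces and rejects the implant axis", {
  m <- build_mesh(geometry_params(block_dims = c(0.012, 0.012, 0.016),
                                  grid_spacing = 0.001))
  expect_length(select_fixed_nodes(m, "x"), 2 * 13 * 17)
  expect_error(select_fixed_nodes(m, "z"), "transverse")
  # degenerate one-cell-wide block: every node is on a clamped face
  m1 <- build_mesh(geometry_params(block_dims = c(0.001, 0.004, 0.006),
                                   grid_spacing = 0.001,
                                   implant_radius = 0.0004,
                                   implant_length = 0.003,
                                   cortical_thickness = 0.001))
  expect_setequal(select_fixed_nodes(m1, "x"), seq_len(nrow(m1$coords)))
})

test_that("geometry invariants are enforced", {
  expect_error(tiny_geometry(grid_spacing = 0.002), "resolution")
  expect_error(tiny_geometry(implant_length = 0.008),
               "block extent along the implant axis")
  expect_error(tiny_geometry(implant_radius = 0.004), "transverse")
  expect_error(tiny_geometry(trabecular_porosity = 1), "porosity")
})

test_that("porosity knockout is deterministic, seed-sensitive and leaves other regions intact", {
  m <- build_mesh(tiny_geometry())
  expect_identical(apply_trabecular_porosity(m, 0, seed = 1), m)
  n_canc <- length(m$element_sets$CANCELLOUS)
  m1 <- apply_trabecular_porosity(m, 0.3, seed = 7)
  m1b <- apply_trabecular_porosity(m, 0.3, seed = 7)
  m2 <- apply_trabecular_porosity(m, 0.3, seed = 8)
  expect_equal(nrow(m$tets) - nrow(m1$tets), round(0.3 * n_canc))
  expect_identical(m1$porosity_removed, m1b$porosity_removed)
  expect_false(identical(m1$porosity_removed, m2$porosity_removed))
  expect_equal(sum(m1$region == "CORTICAL"), sum(m$region == "CORTICAL"))
  expect_equal(sum(m1$region == "IMPLANT"), sum(m$region == "IMPLANT"))
  # soft mode keeps the elements but scales their modulus
  ms <- apply_trabecular_porosity(m, 0.3, seed = 7, mode = "soft")
  expect_equal(nrow(ms$tets), nrow(m$tets))
  expect_equal(sum(ms$modulus_scale == 1e-6), round(0.3 * n_canc))
  # knockout must not disturb the caller's RNG stream
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(apply_trabecular_porosity(m, 0.2, seed = 3))
  expect_identical(runif(1), before)
})

test_that("thread modulation widens the implant at ridge depths and is bounded", {
  smooth <- build_mesh(tiny_geometry(grid_spacing = 5e-4))
  ridged <- build_mesh(tiny_geometry(grid_spacing = 5e-4,
                                     thread_amplitude = 4e-4,
                                     thread_pitch = 2e-3))
  n_s <- length(smooth$element_sets$IMPLANT)
  n_r <- length(ridged$element_sets$IMPLANT)
  expect_true(n_r != n_s)
  p <- ridged$params
  ctr <- p$block_dims / 2
  rdist <- sqrt((ridged$centroids[, 1] - ctr[1])^2 +
                (ridged$centroids[, 2] - ctr[2])^2)
  imp <- ridged$region == "IMPLANT"
  expect_true(all(rdist[imp] <= p$implant_radius + p$thread_amplitude))
  expect_error(tiny_geometry(thread_amplitude = 0.002), "thread_amplitude")
})

test_that("mesh exports are readable text files", {
  m <- build_mesh(tiny_geometry())
  vtk <- tempfile(fileext = ".vtk")
  write_vtk(m, vtk, cell_data = list(vol = tet_volumes(m)))
  lines <- readLines(vtk)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(m$coords)), lines)))
  inp <- tempfile(fileext = ".inp")
  write_abaqus_inp(m, inp)
  lines <- readLines(inp)
  expect_true(any(grepl("\\*ELEMENT, TYPE=C3D4", lines)))
  expect_true(any(grepl("ELSET=CANCELLOUS", lines)))
})
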