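test_that("default meshes hit the requested node count on a closed manifold", {
  mm <- build_cell_meshes(radius_um = 8, node_count = 549)
  for (mesh in mm) {
    n_v <- nrow(mesh$pos)
    n_e <- nrow(mesh$edges)
    n_f <- nrow(mesh$tris)
    expect_identical(n_v, 549L)
    expect_identical(n_v - n_e + n_f, 2L)  # Euler characteristic
    # every edge borders exactly two triangles
    e <- rbind(mesh$tris[, 1:2], mesh$tris[, 2:3], mesh$tris[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(key) == 2))
    expect_true(all(mesh$ref_edge_lengths > 0))
    expect_true(all(mesh$ref_tri_areas > 0))
    expect_equal(rowSums(mesh$node_normals^2), rep(1, n_v), tolerance = 1e-9)
  }
  # coarse-mesh surface area within 5% of the sphere
  expect_equal(sum(mm$cell$tri_areas), 4 * pi * 8000^2, tolerance = 0.05)
  # stress-free as built
  expect_equal(sum(mm$cell$ref_tri_areas), sum(mm$cell$tri_areas))
  # bottom sits one integrin equilibrium distance above the substrate
  expect_equal(min(mm$cell$pos[, 3]), 30, tolerance = 1e-6)
  # nucleus strictly inside the cell
  expect_lt(max(sqrt(rowSums(sweep(mm$nucleus$pos, 2,
                                   colMeans(mm$cell$pos))^2))),
            min(sqrt(rowSums(sweep(mm$cell$pos, 2,
                                   colMeans(mm$cell$pos))^2))))
})

test_that("the icosahedron base case has the textbook element counts", {
  ico <- mechanocell:::icosphere(12)
  expect_identical(nrow(ico$v), 12L)
  expect_identical(nrow(ico$f), 20L)
  expect_identical(nrow(mechanocell:::edges_from_faces(ico$f)), 30L)
  expect_error(mechanocell:::icosphere(11), "node_count")
})

test_that("partial subdivision reaches arbitrary node counts exactly", {
  for (n in c(42, 100, 250, 549, 642)) {
    ic <- mechanocell:::icosphere(n)
    expect_identical(nrow(ic$v), as.integer(n))
    expect_identical(nrow(ic$v) - nrow(mechanocell:::edges_from_faces(ic$f)) +
                       nrow(ic$f), 2L)
  }
})

test_that("differentials scale with similarity and ignore rigid motions", {
  m <- build_cell_meshes(radius_um = 2, node_count = 42)$cell
  m2 <- m
  m2$pos <- m$pos * 2
  m2 <- update_differentials(m2)
  expect_equal(m2$edge_lengths, m$edge_lengths * 2)
  expect_equal(m2$tri_areas, m$tri_areas * 4)
  m3 <- m
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m3$pos <- m$pos %*% t(R) + matrix(c(5, -3, 11), nrow(m$pos), 3,
                                    byrow = TRUE)
  m3 <- update_differentials(m3)
  expect_equal(m3$edge_lengths, m$edge_lengths)
  expect_equal(m3$tri_areas, m$tri_areas)
  # idempotence
  m4 <- update_differentials(m3)
  expect_identical(m4$edge_lengths, m3$edge_lengths)
  # node normals of a full icosphere are radial within 5 degrees
  mu <- build_cell_meshes(radius_um = 1, node_count = 162)$cell
  rad <- sweep(mu$pos, 2, colMeans(mu$pos))
  rad <- rad / sqrt(rowSums(rad^2))
  ang <- acos(pmin(1, rowSums(rad * mu$node_normals))) * 180 / pi
  expect_lt(max(ang), 5)
})

test_that("degenerate triangles are reported by id", {
  m <- build_cell_meshes(radius_um = 1, node_count = 12)$cell
  m$pos[m$tris[1, 2], ] <- m$pos[m$tris[1, 1], ]
  expect_error(update_differentials(m), "degenerate")
})

test_that("compatibility projects penetrating nodes with a 1 nm clearance", {
  mm <- build_cell_meshes(radius_um = 2, node_count = 42)
  cell <- mm$cell
  nucleus <- mm$nucleus
  # no violations: unchanged, count 0
  r0 <- enforce_compatibility(cell, nucleus)
  expect_identical(r0$n_corrections, 0L)
  expect_equal(r0$cell$pos, cell$pos)
  # push a cell node 5 nm below the plane
  i <- which.min(cell$pos[, 3])
  cell2 <- cell
  cell2$pos[i, 3] <- -5
  cell2 <- update_differentials(cell2)
  r1 <- enforce_compatibility(cell2, nucleus)
  expect_equal(r1$cell$pos[i, 3], 1)
  expect_gte(r1$n_corrections, 1L)
  # push a nucleus node outside the cell surface by ~3 nm
  j <- 1L
  ctr <- colMeans(cell$pos)
  dirv <- nucleus$pos[j, ] - ctr
  dirv <- dirv / sqrt(sum(dirv^2))
  nucleus2 <- nucleus
  k <- which.min(rowSums((cell$pos - matrix(nucleus$pos[j, ],
                                            nrow(cell$pos), 3,
                                            byrow = TRUE))^2))
  target <- cell$pos[k, ] + 3 * cell$node_normals[k, ]
  nucleus2$pos[j, ] <- target
  nucleus2 <- update_differentials(nucleus2)
  expect_gt(signed_distance_nearest(nucleus2$pos[j, ], cell), 0)
  r2 <- enforce_compatibility(cell, nucleus2)
  expect_lt(signed_distance_nearest(r2$nucleus$pos[j, ], cell), 0)
  expect_equal(signed_distance_nearest(r2$nucleus$pos[j, ], cell), -1,
               tolerance = 0.5)
})

test_that("mesh writers emit valid ASCII PLY and VTK", {
  m <- build_cell_meshes(radius_um = 1, node_count = 12)$cell
  f1 <- tempfile(fileext = ".ply")
  f2 <- tempfile(fileext = ".vtk")
  write_mesh_ply(m, f1)
  write_mesh_vtk(m, f2, point_data = list(n_b = seq_len(12)))
  ply <- readLines(f1)
  expect_identical(ply[1], "ply")
  expect_identical(sum(ply == "end_header"), 1L)
  expect_length(ply, 9 + 12 + 20)
  vtk <- readLines(f2)
  expect_identical(vtk[4], "DATASET POLYDATA")
  expect_true(any(grepl("^POINT_DATA 12", vtk)))
  expect_true(any(grepl("^SCALARS n_b", vtk)))
})
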