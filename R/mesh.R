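#' Triangulated membrane meshes
#'
#' A `tri_mesh` is a closed, orientable triangulated surface used for both the
#' cell (cortical) membrane and the nuclear membrane. Node positions are in nm.
#' Reference (relaxed) edge lengths and triangle areas are frozen at build time
#' and define the stress-free state of the elastic network; `ref_pos` stores the
#' build-time node positions and is the reference configuration for the surface
#' strain tensor.
#'
#' @name tri_mesh
NULL

golden <- (1 + sqrt(5)) / 2

icosahedron <- function() {
  p <- golden
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(v = v, f = f)
}

edges_from_faces <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Split the edges listed in `split_idx` (indices into the canonical edge list),
# re-triangulating each face by the 1/2/3-split templates. Midpoints are
# projected back to the unit sphere. Keeps outward CCW orientation.
subdivide_edges <- function(v, f, split_idx) {
  e <- edges_from_faces(f)
  ne <- nrow(e)
  mid_id <- integer(ne)                 # 0 = not split
  nv0 <- nrow(v)
  newv <- matrix(0, length(split_idx), 3)
  for (k in seq_along(split_idx)) {
    i <- split_idx[k]
    m <- (v[e[i, 1], ] + v[e[i, 2], ]) / 2
    newv[k, ] <- m / sqrt(sum(m^2))
    mid_id[i] <- nv0 + k
  }
  ekey <- e[, 1] * (nv0 + 1) + e[, 2]
  lookup <- function(a, b) {
    key <- min(a, b) * (nv0 + 1) + max(a, b)
    mid_id[match(key, ekey)]
  }
  out <- vector("list", nrow(f))
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    mab <- lookup(a, b); mbc <- lookup(b, c); mca <- lookup(c, a)
    s <- c(mab > 0, mbc > 0, mca > 0)
    out[[t]] <-
      if (!any(s)) rbind(c(a, b, c))
      else if (all(s)) rbind(c(a, mab, mca), c(mab, b, mbc),
                             c(mca, mbc, c), c(mab, mbc, mca))
      else if (s[1] && s[2]) rbind(c(mab, b, mbc), c(a, mab, mbc), c(a, mbc, c))
      else if (s[2] && s[3]) rbind(c(a, b, mbc), c(a, mbc, mca), c(mbc, c, mca))
      else if (s[1] && s[3]) rbind(c(a, mab, mca), c(mab, b, c), c(mab, c, mca))
      else if (s[1]) rbind(c(a, mab, c), c(mab, b, c))
      else if (s[2]) rbind(c(a, b, mbc), c(a, mbc, c))
      else rbind(c(a, b, mca), c(mca, b, c))
  }
  list(v = rbind(v, newv), f = do.call(rbind, out))
}

#' Unit icosphere with an exact node count
#'
#' Subdivided icosahedron supporting partial (edge-split) subdivision, so any
#' node count from 12 up is reachable exactly: full Loop-style subdivisions
#' give 12, 42, 162, 642, ... nodes, and splitting k of the E edges of the
#' last full level adds exactly k nodes. Split edges are spread evenly through
#' the canonical edge ordering.
#'
#' @param n_target desired number of nodes (>= 12)
#' @return list with unit-sphere vertex matrix `v` and face index matrix `f`
#' @keywords internal
icosphere <- function(n_target) {
  if (n_target < 12) stop("node_count must be >= 12 (icosahedron)")
  m <- icosahedron()
  repeat {
    ne <- nrow(edges_from_faces(m$f))
    n_full <- nrow(m$v) + ne
    if (n_full > n_target) break
    m <- subdivide_edges(m$v, m$f, seq_len(ne))
  }
  k <- n_target - nrow(m$v)
  if (k > 0) {
    ne <- nrow(edges_from_faces(m$f))
    idx <- unique(round(seq(1, ne, length.out = k)))
    # rounding collisions are impossible for k <= ne, but guard anyway
    while (length(idx) < k) idx <- union(idx, setdiff(seq_len(ne), idx)[1])
    m <- subdivide_edges(m$v, m$f, sort(idx))
  }
  m
}

new_tri_mesh <- function(pos, tris) {
  mesh <- structure(list(
    pos = pos,
    edges = edges_from_faces(tris),
    tris = tris,
    ref_pos = pos,
    ref_edge_lengths = NULL,
    ref_tri_areas = NULL
  ), class = "tri_mesh")
  mesh <- update_differentials(mesh)
  mesh$ref_edge_lengths <- mesh$edge_lengths
  mesh$ref_tri_areas <- mesh$tri_areas
  mesh
}

#' Recompute differential quantities of a mesh
#'
#' Updates edge lengths, triangle areas and outward node normals from the
#' current node positions. Node normals are the area-weighted average of the
#' incident triangle normals, renormalized. Idempotent and invariant under
#' rigid motions.
#'
#' @param mesh a [tri_mesh]
#' @return the mesh with `edge_lengths`, `tri_areas`, `tri_normals`,
#'   `node_normals` refreshed
#' @export
update_differentials <- function(mesh) {
  p <- mesh$pos
  tr <- mesh$tris
  u <- p[tr[, 2], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  v <- p[tr[, 3], , drop = FALSE] - p[tr[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm2 <- sqrt(rowSums(cr^2))
  if (any(nrm2 <= 0)) {
    stop("degenerate (zero-area) triangle: ",
         paste(which(nrm2 <= 0), collapse = ", "))
  }
  mesh$tri_areas <- nrm2 / 2
  mesh$tri_normals <- cr / nrm2
  d <- p[mesh$edges[, 1], , drop = FALSE] - p[mesh$edges[, 2], , drop = FALSE]
  mesh$edge_lengths <- sqrt(rowSums(d^2))
  nn <- matrix(0, nrow(p), 3)
  w <- mesh$tri_areas
  for (j in 1:3) {
    for (ax in 1:3) {
      nn[, ax] <- nn[, ax] +
        tapply_add(tr[, j], w * mesh$tri_normals[, ax], nrow(p))
    }
  }
  len <- sqrt(rowSums(nn^2))
  len[len == 0] <- 1
  mesh$node_normals <- nn / len
  mesh
}

# sum `val` into bins `idx` of length n (dense tabulate-style accumulator)
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "tri_mesh: %d nodes, %d edges, %d triangles (Euler chi = %d)\n",
    nrow(x$pos), nrow(x$edges), nrow(x$tris),
    nrow(x$pos) - nrow(x$edges) + nrow(x$tris)))
  cat(sprintf("  total area %.3f um^2, total ref area %.3f um^2\n",
              sum(x$tri_areas) / 1e6, sum(x$ref_tri_areas) / 1e6))
  invisible(x)
}

#' Build concentric cell and nucleus membrane meshes
#'
#' Both membranes start round (spheres), concentric, with the cell bottom
#' sitting a gap of `gap_nm` above the substrate plane z = 0 so that adhesion
#' can begin immediately (the gap equals the integrin equilibrium distance,
#' 30 nm, well under the 300 nm bonding ceiling). Reference lengths and areas
#' are set to the as-built values, so the initial state is stress free.
#'
#' The tessellation is a subdivided icosahedron with partial edge-split
#' subdivision, so the requested node count (default 549 nodes per membrane,
#' carrying 164,700/549 = 300 integrins per cortical node) is met exactly.
#'
#' @param radius_um cell radius in micrometers (default 8)
#' @param node_count nodes per membrane (default 549)
#' @param nucleus_ratio nucleus radius / cell radius (default 0.45)
#' @param gap_nm initial gap between cell bottom and substrate (default 30)
#' @return list with elements `cell` and `nucleus`, both [tri_mesh]
#' @export
build_cell_meshes <- function(radius_um = 8, node_count = 549,
                              nucleus_ratio = 0.45, gap_nm = 30) {
  stopifnot(radius_um > 0, nucleus_ratio > 0, nucleus_ratio < 1)
  ico <- icosphere(node_count)
  r_cell <- radius_um * 1000
  r_nuc <- nucleus_ratio * r_cell
  center <- c(0, 0, r_cell + gap_nm)
  cell <- new_tri_mesh(ico$v * r_cell +
                         matrix(center, nrow(ico$v), 3, byrow = TRUE), ico$f)
  nucleus <- new_tri_mesh(ico$v * r_nuc +
                            matrix(center, nrow(ico$v), 3, byrow = TRUE), ico$f)
  list(cell = cell, nucleus = nucleus)
}

#' Resolve geometric incompatibilities between meshes and substrate
#'
#' Node positions updated by the equations of motion can occasionally place
#' cell membrane nodes below the substrate or nuclear nodes outside the cell
#' membrane; these configurations are corrected every cycle. A penetrating
#' cell node is projected back onto the substrate surface plus a 1 nm
#' clearance along the substrate normal; a nuclear node outside the cortex is
#' pulled inward along the local cortical normal by the violation depth plus
#' 1 nm. The outside test uses the tangent plane of the nearest cortical node.
#'
#' @param cell,nucleus [tri_mesh] objects (differentials current)
#' @param substrate_z substrate plane height in nm (default 0); `NULL` skips
#'   the substrate check
#' @param clearance_nm clearance after correction (default 1)
#' @param max_iter maximum correction sweeps before erroring (default 10)
#' @return list `cell`, `nucleus`, `n_corrections`
#' @export
enforce_compatibility <- function(cell, nucleus, substrate_z = 0,
                                  clearance_nm = 1, max_iter = 10) {
  n_corr <- 0L
  if (!is.null(substrate_z)) {
    below <- cell$pos[, 3] < substrate_z
    if (any(below)) {
      cell$pos[below, 3] <- substrate_z + clearance_nm
      n_corr <- n_corr + sum(below)
      cell <- update_differentials(cell)
    }
    belown <- nucleus$pos[, 3] < substrate_z
    if (any(belown)) {
      nucleus$pos[belown, 3] <- substrate_z + clearance_nm
      n_corr <- n_corr + sum(belown)
    }
  }
  for (it in seq_len(max_iter)) {
    viol <- FALSE
    for (i in seq_len(nrow(nucleus$pos))) {
      d2 <- rowSums((cell$pos -
                       matrix(nucleus$pos[i, ], nrow(cell$pos), 3,
                              byrow = TRUE))^2)
      j <- which.min(d2)
      nrm <- cell$node_normals[j, ]
      depth <- sum((nucleus$pos[i, ] - cell$pos[j, ]) * nrm)
      if (depth > 0) {
        nucleus$pos[i, ] <- nucleus$pos[i, ] - (depth + clearance_nm) * nrm
        n_corr <- n_corr + 1L
        viol <- TRUE
      }
    }
    if (!viol) break
    if (it == max_iter) stop("compatibility not resolvable after ",
                             max_iter, " iterations")
  }
  nucleus <- update_differentials(nucleus)
  list(cell = cell, nucleus = nucleus, n_corrections = n_corr)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [tri_mesh]
#' @param file output path
#' @export
write_mesh_ply <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$pos)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$tris)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh$pos, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh$tris - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Write a mesh as legacy ASCII VTK POLYDATA
#'
#' Optional per-node scalar fields (e.g. bond count, traction magnitude) are
#' attached as POINT_DATA.
#'
#' @param mesh a [tri_mesh]
#' @param file output path
#' @param point_data named list of numeric vectors (one value per node)
#' @export
write_mesh_vtk <- function(mesh, file, point_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  nv <- nrow(mesh$pos); nf <- nrow(mesh$tris)
  writeLines(c("# vtk DataFile Version 3.0", "mechanocell mesh frame",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nv)), con)
  write.table(format(mesh$pos, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  write.table(cbind(3L, mesh$tris - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], trim = TRUE), con)
    }
  }
}
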