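# Shared oracles and fixture builders (all fixtures are built in code).

# brute-force signed distance of a point to a closed mesh: distance to the
# nearest node, signed by that node's outward normal (adequate for the
# near-surface queries used in the compatibility tests)
signed_distance_nearest <- function(point, mesh) {
  d2 <- rowSums((mesh$pos - matrix(point, nrow(mesh$pos), 3, byrow = TRUE))^2)
  j <- which.min(d2)
  sum((point - mesh$pos[j, ]) * mesh$node_normals[j, ])
}

# central finite-difference gradient of the total elastic energy
fd_elastic_forces <- function(mesh, k_line, k_area, h = 1e-3) {
  energy <- function(p) {
    mm <- mesh
    mm$pos <- p
    mm <- update_differentials(mm)
    line_energy(mm, k_line) + area_energy(mm, k_area)
  }
  out <- matrix(0, nrow(mesh$pos), 3)
  for (i in seq_len(nrow(mesh$pos))) {
    for (ax in 1:3) {
      p1 <- mesh$pos
      p2 <- mesh$pos
      p1[i, ax] <- p1[i, ax] + h
      p2[i, ax] <- p2[i, ax] - h
      out[i, ax] <- -(energy(p1) - energy(p2)) / (2 * h)
    }
  }
  out
}

# a small flat triangulated sheet as a tri_mesh-like object for strain tests
flat_sheet_mesh <- function(n = 4, spacing = 100) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  pos <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(i, j) j * n + i + 1L
  tris <- do.call(rbind, lapply(0:(n - 2), function(j) {
    do.call(rbind, lapply(0:(n - 2), function(i) {
      rbind(c(id(i, j), id(i + 1, j), id(i, j + 1)),
            c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
    }))
  }))
  mesh <- structure(list(pos = pos, tris = tris,
                         edges = unique(cbind(
                           pmin(rbind(tris[, 1:2], tris[, 2:3],
                                      tris[, c(3, 1)])[, 1],
                                rbind(tris[, 1:2], tris[, 2:3],
                                      tris[, c(3, 1)])[, 2]),
                           pmax(rbind(tris[, 1:2], tris[, 2:3],
                                      tris[, c(3, 1)])[, 1],
                                rbind(tris[, 1:2], tris[, 2:3],
                                      tris[, c(3, 1)])[, 2]))),
                         ref_pos = pos),
                    class = "tri_mesh")
  mesh <- update_differentials(mesh)
  mesh$ref_edge_lengths <- mesh$edge_lengths
  mesh$ref_tri_areas <- mesh$tri_areas
  mesh
}

# short cached simulation runs shared across test files (computed on first use)
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}
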