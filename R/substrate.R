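#' Ligand fields on planar substrates and micropatterns
#'
#' The substrate is a planar (z = 0) surface triangulated into near-equilateral
#' triangles of side ~0.75 um (element area ~0.243 um^2). Each triangle carries
#' an integer pool of fibronectin ligands: `init` molecules seeded at build
#' time as `round(c_L * A_L)` inside the pattern mask (zero outside), of which
#' `free` are currently unbound. Bound ligands return to the free pool when
#' their bond ruptures, so free + bound = init per triangle at all times.
#'
#' @name ligand_field
NULL

# Row-major regular triangulation over [x0, x0+W] x [y0, y0+H]; odd vertex rows
# offset by half a spacing. Strips of 2*(nx-1) triangles per row pair allow
# O(1) point location.
triangulate_plane <- function(x0, y0, width, height, side = 0.75) {
  dx <- side
  dy <- side * sqrt(3) / 2
  nx <- max(2L, ceiling(width / dx) + 1L)
  ny <- max(2L, ceiling(height / dy) + 1L)
  j <- rep(0:(ny - 1), each = nx)
  i <- rep(0:(nx - 1), ny)
  vx <- x0 + (i + 0.5 * (j %% 2)) * dx
  vy <- y0 + j * dy
  vid <- function(jj, ii) jj * nx + ii + 1L
  tris <- vector("list", ny - 1)
  for (jj in 0:(ny - 2)) {
    ii <- 0:(nx - 2)
    if (jj %% 2 == 0) {
      a <- rbind(vid(jj, ii), vid(jj, ii + 1), vid(jj + 1, ii))
      b <- rbind(vid(jj, ii + 1), vid(jj + 1, ii + 1), vid(jj + 1, ii))
    } else {
      a <- rbind(vid(jj, ii), vid(jj, ii + 1), vid(jj + 1, ii + 1))
      b <- rbind(vid(jj, ii), vid(jj + 1, ii + 1), vid(jj + 1, ii))
    }
    m <- matrix(0L, 2 * (nx - 1), 3)
    m[seq(1, nrow(m), 2), ] <- t(a)
    m[seq(2, nrow(m), 2), ] <- t(b)
    tris[[jj + 1]] <- m
  }
  tris <- do.call(rbind, tris)
  verts <- cbind(vx, vy)
  cx <- (verts[tris[, 1], 1] + verts[tris[, 2], 1] + verts[tris[, 3], 1]) / 3
  cy <- (verts[tris[, 1], 2] + verts[tris[, 2], 2] + verts[tris[, 3], 2]) / 3
  ar <- abs((verts[tris[, 2], 1] - verts[tris[, 1], 1]) *
              (verts[tris[, 3], 2] - verts[tris[, 1], 2]) -
              (verts[tris[, 3], 1] - verts[tris[, 1], 1]) *
              (verts[tris[, 2], 2] - verts[tris[, 1], 2])) / 2
  list(verts = verts, tris = tris, centroid = cbind(cx, cy), area = ar,
       x0 = x0, y0 = y0, dx = dx, dy = dy, nx = nx, ny = ny)
}

new_ligand_field <- function(geom, mask, c_L) {
  init <- ifelse(mask, as.integer(round(c_L * geom$area)), 0L)
  structure(list(
    verts = geom$verts, tris = geom$tris, centroid = geom$centroid,
    area = geom$area, mask = mask, init = init, free = init,
    c_L = c_L, x0 = geom$x0, y0 = geom$y0, dx = geom$dx, dy = geom$dy,
    nx = geom$nx, ny = geom$ny
  ), class = "ligand_field")
}

#' @export
print.ligand_field <- function(x, ...) {
  cat(sprintf(
    "ligand_field: %d triangles (A_L ~ %.4f um^2), c_L = %g molecules/um^2\n",
    length(x$area), mean(x$area), x$c_L))
  cat(sprintf("  pattern area %.1f um^2, %d ligands total (%d free)\n",
              sum(x$area[x$mask]), sum(x$init), sum(x$free)))
  invisible(x)
}

#' Build a uniformly coated planar ligand field
#'
#' @param extent_um side of the square field, centered at the origin
#'   (default 200, covering the migration range)
#' @param c_L ligand surface density in molecules/um^2
#' @param side_um triangle side length (default 0.75)
#' @return a [ligand_field]
#' @export
build_planar_field <- function(extent_um = 200, c_L, side_um = 0.75) {
  stopifnot(c_L >= 0)
  g <- triangulate_plane(-extent_um / 2, -extent_um / 2,
                         extent_um, extent_um, side_um)
  new_ligand_field(g, rep(TRUE, length(g$area)), c_L)
}

#' Build a micropatterned ligand field
#'
#' Ligands (and hence adhesion and protrusion) exist only inside the pattern
#' mask; outside it the ligand density is zero. Supported shapes, all centered
#' at the origin:
#' \describe{
#'   \item{disk}{full circle, `diameter_um` (default 6).}
#'   \item{pacman}{circle minus a wedge of opening `wedge_deg` (default 90)
#'     centered on the +y axis.}
#'   \item{crossbow}{a 180-degree circular-arc roof (outer diameter
#'     `diameter_um`, thickness `arc_thickness_um`, default 2) over the upper
#'     half plane, plus a vertical bar (`bar_length_um` x `bar_width_um`,
#'     default 4 x 2) hanging from the arc's inner radius.}
#' }
#'
#' Default dimensions follow the sizing rule that the pattern area should be
#' comparable to the model cell's free-spread contact area (~28 um^2), so the
#' pattern geometry actually constrains adhesion; all dimensions are
#' configurable.
#'
#' @param shape one of "disk", "pacman", "crossbow"
#' @param c_L ligand surface density in molecules/um^2
#' @param diameter_um circumscribing disk diameter (default 6)
#' @param wedge_deg pacman wedge opening in degrees (default 90)
#' @param arc_thickness_um,bar_length_um,bar_width_um crossbow dimensions
#' @param margin_um uncoated margin triangulated around the pattern
#'   (default 10)
#' @param side_um triangle side length (default 0.75)
#' @return a [ligand_field]
#' @export
build_micropattern_field <- function(shape = c("disk", "pacman", "crossbow"),
                                     c_L, diameter_um = 6, wedge_deg = 90,
                                     arc_thickness_um = 2, bar_length_um = 4,
                                     bar_width_um = 2, margin_um = 10,
                                     side_um = 0.75) {
  shape <- match.arg(shape)
  stopifnot(c_L >= 0, diameter_um > 0)
  if (shape == "pacman" && (wedge_deg < 0 || wedge_deg >= 360)) {
    stop("pacman wedge must be in [0, 360) degrees")
  }
  if (shape == "crossbow" && (bar_width_um <= 0 || arc_thickness_um <= 0)) {
    stop("crossbow bar width and arc thickness must be positive")
  }
  half <- diameter_um / 2 + margin_um
  g <- triangulate_plane(-half, -half, 2 * half, 2 * half, side_um)
  x <- g$centroid[, 1]; y <- g$centroid[, 2]
  r <- sqrt(x^2 + y^2)
  R <- diameter_um / 2
  mask <- switch(shape,
    disk = r <= R,
    pacman = {
      ang <- abs(atan2(x, y))               # angle from +y axis
      r <= R & !(ang < (wedge_deg * pi / 180) / 2)
    },
    crossbow = {
      arc <- r <= R & r >= R - arc_thickness_um & y >= 0
      bar_top <- R - arc_thickness_um
      bar <- abs(x) <= bar_width_um / 2 &
        y <= bar_top & y >= bar_top - bar_length_um
      arc | bar
    })
  new_ligand_field(g, mask, c_L)
}

#' Convert fibronectin plating concentration to ligand surface density
#'
#' Piecewise-linear interpolation through the calibration pairs
#' (1, 19.4), (10, 192), (30, 568), (60, 1140), (80, 1522) in
#' (ug/mL, molecules/um^2), anchored at (0, 0). Concentrations above
#' 80 ug/mL are extrapolated with the last segment's slope (with a warning).
#'
#' @param conc_ug_per_ml plating concentration(s), ug/mL
#' @return ligand surface density, molecules/um^2
#' @export
plating_to_density <- function(conc_ug_per_ml) {
  if (any(conc_ug_per_ml < 0)) stop("plating concentration must be >= 0")
  xs <- c(0, 1, 10, 30, 60, 80)
  ys <- c(0, 19.4, 192, 568, 1140, 1522)
  out <- stats::approx(xs, ys, xout = pmin(conc_ug_per_ml, 80))$y
  hi <- conc_ug_per_ml > 80
  if (any(hi)) {
    warning("extrapolating ligand density above the 80 ug/mL calibration range")
    slope <- (ys[6] - ys[5]) / (xs[6] - xs[5])
    out[hi] <- ys[6] + slope * (conc_ug_per_ml[hi] - 80)
  }
  out
}

# O(1) point location in the regular triangulation; returns triangle id or NA
field_locate <- function(field, x_um, y_um) {
  jr <- floor((y_um - field$y0) / field$dy)
  ic <- floor((x_um - field$x0) / field$dx)
  nxm <- field$nx - 1L
  if (is.na(jr) || jr < 0 || jr > field$ny - 2L) return(NA_integer_)
  cand <- integer(0)
  for (cc in (ic - 1L):(ic + 1L)) {
    if (cc < 0 || cc > nxm - 1L) next
    base <- jr * 2L * nxm + 2L * cc
    cand <- c(cand, base + 1L, base + 2L)
  }
  for (tid in cand) {
    v <- field$verts[field$tris[tid, ], , drop = FALSE]
    d <- (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])
    l1 <- ((v[2, 2] - v[3, 2]) * (x_um - v[3, 1]) +
             (v[3, 1] - v[2, 1]) * (y_um - v[3, 2])) / d
    l2 <- ((v[3, 2] - v[1, 2]) * (x_um - v[3, 1]) +
             (v[1, 1] - v[3, 1]) * (y_um - v[3, 2])) / d
    l3 <- 1 - l1 - l2
    if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) return(tid)
  }
  NA_integer_
}

#' Project an integrin node onto the substrate
#'
#' Casts a ray from the node toward the substrate along the outward membrane
#' normal (which points downward, toward the substrate, for ventral nodes);
#' when the normal grazes the surface (|n_z| < 0.2) a vertical ray is used
#' instead. The hit point is the bond root x_L. The node is eligible for
#' bonding iff the orientation condition holds (outward normal opposing the
#' substrate normal, n_z < 0), the gap h_p is under the critical height
#' h_c = 300 nm, and the hit triangle lies inside the pattern mask.
#'
#' @param node_pos node position, nm (z >= 0 above the substrate plane z = 0)
#' @param node_normal outward unit normal at the node
#' @param field a [ligand_field]
#' @param h_c_nm critical bonding height (default 300)
#' @return list with `triangle_id`, `gap_nm`, `root` (nm) and `eligible`
#' @export
project_node <- function(node_pos, node_normal, field, h_c_nm = 300) {
  nz <- node_normal[3]
  res <- list(triangle_id = NA_integer_, gap_nm = NA_real_,
              root = NULL, eligible = FALSE)
  if (nz >= 0) return(res)                      # orientation condition fails
  d <- if (nz > -0.2) c(0, 0, -1) else node_normal
  t_hit <- -node_pos[3] / d[3]
  root <- node_pos + t_hit * d
  tid <- field_locate(field, root[1] / 1000, root[2] / 1000)
  res$gap_nm <- t_hit
  res$root <- root
  res$triangle_id <- tid
  res$eligible <- !is.na(tid) && field$mask[tid] && t_hit < h_c_nm
  res
}

#' Write a ligand field as legacy ASCII VTK with per-triangle ligand counts
#'
#' @param field a [ligand_field]
#' @param file output path
#' @export
write_field_vtk <- function(field, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nv <- nrow(field$verts); nf <- nrow(field$tris)
  writeLines(c("# vtk DataFile Version 3.0", "mechanocell ligand field",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nv)), con)
  write.table(cbind(format(field$verts, trim = TRUE), 0), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  write.table(cbind(3L, field$tris - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_DATA %d", nf), con)
  writeLines(c("SCALARS free_ligands int 1", "LOOKUP_TABLE default"), con)
  writeLines(format(field$free), con)
}
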