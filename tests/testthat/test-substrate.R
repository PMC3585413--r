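test_that("planar field triangles match the 0.243 um^2 ligand element", {
  f <- build_planar_field(extent_um = 10, c_L = 1140)
  expect_equal(mean(f$area), sqrt(3) / 4 * 0.75^2, tolerance = 0.01)
  # side lengths within 25% of 0.75 um
  for (k in 1:3) {
    a <- f$verts[f$tris[, k], ]
    b <- f$verts[f$tris[, k %% 3 + 1], ]
    side <- sqrt(rowSums((a - b)^2))
    expect_true(all(side > 0.75 * 0.75 & side < 1.25 * 0.75))
  }
  # seeded counts: round(c_L * A_L)
  expect_identical(f$init, as.integer(round(1140 * f$area)))
  expect_true(all(f$init %in% c(277L, 278L)))  # 1140 x 0.2436 = 277.7
  expect_identical(f$free, f$init)
  f0 <- build_planar_field(extent_um = 5, c_L = 0)
  expect_true(all(f0$init == 0L))
})

test_that("micropattern masks carry ligand only inside the pattern", {
  fd <- build_micropattern_field("disk", c_L = 475)
  fp0 <- build_micropattern_field("pacman", c_L = 475, wedge_deg = 0)
  expect_identical(fd$mask, fp0$mask)  # zero-wedge pacman is a disk
  fp <- build_micropattern_field("pacman", c_L = 475, wedge_deg = 90)
  expect_lt(sum(fp$mask), sum(fd$mask))
  # density inside 475, outside 0
  expect_true(all(fd$init[!fd$mask] == 0L))
  expect_equal(mean(fd$init[fd$mask] / fd$area[fd$mask]), 475,
               tolerance = 0.01)
  # total count = density x pattern area within rounding (<= 1 per triangle)
  expect_lt(abs(sum(fd$init) - 475 * sum(fd$area[fd$mask])),
            sum(fd$mask) * 0.5 + 1)
  # pattern areas: disk > pacman; crossbow is arc + bar
  fc <- build_micropattern_field("crossbow", c_L = 475)
  expect_gt(sum(fc$mask), 0)
  expect_lt(sum(fc$area[fc$mask]), sum(fd$area[fd$mask]))
  expect_error(build_micropattern_field("pacman", c_L = 1, wedge_deg = 360),
               "wedge")
  expect_error(build_micropattern_field("crossbow", c_L = 1, bar_width_um = 0),
               "width")
})

test_that("plating-to-density calibration is exact and monotone", {
  conc <- c(1, 10, 30, 60, 80)
  dens <- c(19.4, 192, 568, 1140, 1522)
  expect_equal(plating_to_density(conc), dens)
  expect_equal(plating_to_density(0), 0)
  # 25 ug/mL interpolates within 1 molecule/um^2 of the printed 475
  expect_lte(abs(plating_to_density(25) - 475), 1)
  expect_equal(plating_to_density(25), 474)  # exact linear interpolant
  grid <- seq(0, 79, by = 0.5)
  expect_true(all(diff(plating_to_density(grid)) >= 0))
  expect_error(plating_to_density(-1), ">= 0")
  expect_warning(plating_to_density(100), "extrapolating")
})

test_that("node projection gates on orientation, gap and mask", {
  f <- build_planar_field(extent_um = 10, c_L = 100)
  # straight-down normal, 100 nm gap
  r <- project_node(c(0, 0, 100), c(0, 0, -1), f)
  expect_true(r$eligible)
  expect_equal(r$gap_nm, 100)
  expect_equal(r$root, c(0, 0, 0))
  # gap beyond the 300 nm critical height
  r2 <- project_node(c(0, 0, 350), c(0, 0, -1), f)
  expect_false(r2$eligible)
  # upward normal: orientation condition fails
  r3 <- project_node(c(0, 0, 100), c(0, 0, 1), f)
  expect_false(r3$eligible)
  # oblique normal: root shifts along the ray
  nrm <- c(sin(0.3), 0, -cos(0.3))
  r4 <- project_node(c(0, 0, 100), nrm, f)
  expect_true(r4$eligible)
  expect_equal(r4$gap_nm, 100 / cos(0.3))
  expect_equal(r4$root[1], 100 * tan(0.3))
  # grazing normal falls back to a vertical ray
  nrm5 <- c(sqrt(1 - 0.01), 0, -0.1)
  r5 <- project_node(c(0, 0, 100), nrm5, f)
  expect_equal(r5$gap_nm, 100)
  # over the pacman wedge: outside the mask, ineligible
  fp <- build_micropattern_field("pacman", c_L = 475, wedge_deg = 90,
                                 diameter_um = 36)
  r6 <- project_node(c(0, 10000, 100), c(0, 0, -1), fp)  # wedge on +y
  expect_false(r6$eligible)
  r7 <- project_node(c(0, -10000, 100), c(0, 0, -1), fp)
  expect_true(r7$eligible)
  # defaults respect the bonding ceiling h_c <= 10 lambda (300 = 10 x 30 nm;
  # the equilibrium distance itself is quoted as 20-30 nm)
  expect_lte(300, 10 * 30)
})

test_that("point location agrees with brute-force barycentric search", {
  f <- build_planar_field(extent_um = 6, c_L = 1)
  set.seed(1)
  pts <- cbind(runif(50, -2.5, 2.5), runif(50, -2.5, 2.5))
  for (i in seq_len(nrow(pts))) {
    tid <- mechanocell:::field_locate(f, pts[i, 1], pts[i, 2])
    expect_false(is.na(tid))
    v <- f$verts[f$tris[tid, ], ]
    d <- (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])
    l1 <- ((v[2, 2] - v[3, 2]) * (pts[i, 1] - v[3, 1]) +
             (v[3, 1] - v[2, 1]) * (pts[i, 2] - v[3, 2])) / d
    l2 <- ((v[3, 2] - v[1, 2]) * (pts[i, 1] - v[3, 1]) +
             (v[1, 1] - v[3, 1]) * (pts[i, 2] - v[3, 2])) / d
    expect_true(l1 >= -1e-6 && l2 >= -1e-6 && 1 - l1 - l2 >= -1e-6)
  }
})
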