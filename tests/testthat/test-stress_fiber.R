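test_that("nuclear SF nucleation picks the nearest nuclear node", {
  mm <- build_cell_meshes(radius_um = 8, node_count = 162)
  # integrin node closest to the +x axis through the common center
  ctr <- colMeans(mm$cell$pos)
  i <- which.max(mm$cell$pos[, 1])
  sf <- nucleate_nuclear_sf(i, mm$cell$pos[i, ], mm$nucleus)
  # the chosen nuclear node is the +x pole of the nucleus
  expect_equal(sf$end_b, which.max(mm$nucleus$pos[, 1]))
  # compartment count: distance in 800 nm units
  d <- sqrt(sum((mm$cell$pos[i, ] - mm$nucleus$pos[sf$end_b, ])^2))
  expect_identical(sf$N_sf, max(1L, as.integer(round(d / 800))))
  expect_identical(sf$phase, "polymerizing")
  # direct compartment-count cases
  expect_identical(mechanocell:::new_stress_fiber("nuclear", 1, 2, 4000)$N_sf,
                   5L)
  expect_identical(mechanocell:::new_stress_fiber("nuclear", 1, 2, 300)$N_sf,
                   1L)
})

test_that("ventral SF pairing follows the lower principal strain direction", {
  m <- flat_sheet_mesh(11, 1000)  # 10 x 10 um sheet
  # stretch along y so the lower principal direction is x
  m$pos[, 2] <- m$pos[, 2] * 1.1
  m <- update_differentials(m)
  s <- surface_strain(m)
  seed_node <- 61L  # mid-sheet: column 5, row 5
  dir_min <- s$dir_min[seed_node, ]
  expect_equal(abs(dir_min[1]), 1, tolerance = 1e-9)
  # no other FA nodes: no fiber
  expect_null(nucleate_ventral_sf(seed_node, m, dir_min, integer(0)))
  # partner along x at 5 um: accepted
  along <- 66L  # same row, 5 columns to the right
  sf <- nucleate_ventral_sf(seed_node, m, dir_min, along)
  expect_identical(sf$end_b, along)
  expect_identical(sf$kind, "ventral")
  # candidate at 90 degrees: rejected
  perp <- 61L + 5L * 11L  # same column, 5 rows up
  expect_null(nucleate_ventral_sf(seed_node, m, dir_min, perp))
  # best-aligned wins when both are admissible
  sf2 <- nucleate_ventral_sf(seed_node, m, dir_min, c(along, perp))
  expect_identical(sf2$end_b, along)
  # distance window: partner beyond 40 um rejected
  mbig <- flat_sheet_mesh(3, 45000)
  expect_null(nucleate_ventral_sf(1L, mbig, c(1, 0, 0), 2L))
})

test_that("unit stiffness is E A / L with the 0.196 um^2 cross-section", {
  p <- sf_params()
  expect_equal(p$A_SF / 1e6, 0.196, tolerance = 0.01)  # nm^2 -> um^2
  expect_equal(sf_unit_stiffness(800, p), 0.23 * pi * 250^2 / 800)
  expect_equal(sf_unit_stiffness(800, p), 56.45, tolerance = 1e-3)
  expect_equal(sf_unit_stiffness(400, p), 2 * sf_unit_stiffness(800, p))
})

test_that("Hill velocity honors its endpoint and monotonicity contracts", {
  p <- sf_params()
  expect_equal(hill_velocity(0, p), 10)
  expect_equal(hill_velocity(p$F_m, p), 0)
  expect_equal(hill_velocity(2 * p$F_m, p), 0)  # clamped beyond stall
  v <- hill_velocity(seq(0, p$F_m, length.out = 50), p)
  expect_true(all(diff(v) < 0))
})

test_that("contraction shortens at twice the sliding rate down to the floor", {
  p <- sf_params()
  sf <- mechanocell:::new_stress_fiber("nuclear", 1, 2, 4000, p)
  sf$phase <- "motor"
  sf1 <- advance_contraction(sf, 0, 1, p)
  expect_equal(sf1$L_a0, 800 - 20)  # 2 x 10 nm/s x 1 s
  # unloaded: the 60% floor (480 nm) is reached in exactly 16 s
  sfx <- sf
  t <- 0
  while (sfx$L_a0 > 0.6 * 800 + 1e-9) {
    sfx <- advance_contraction(sfx, 0, 0.01, p)
    t <- t + 0.01
  }
  expect_equal(t, 16, tolerance = 1e-3)
  expect_equal(sfx$L_a0, 480)
  # at stall: no shortening
  sfs <- advance_contraction(sf, p$F_m, 1, p)
  expect_equal(sfs$L_a0, 800)
})

test_that("SF forces are a tension-only Newton pair along the axis", {
  p <- sf_params()
  sf <- mechanocell:::new_stress_fiber("nuclear", 1, 2, 4000, p)
  sf$phase <- "motor"
  # at rest length: zero pair
  r0 <- sf_forces(sf, c(0, 0, 0), c(sf$N_sf * sf$L_a0, 0, 0), p)
  expect_equal(r0$tension, 0)
  expect_equal(r0$force_a, c(0, 0, 0))
  # shorter than rest: still zero (no pushing)
  rc <- sf_forces(sf, c(0, 0, 0), c(1000, 0, 0), p)
  expect_equal(rc$tension, 0)
  # stretched along an arbitrary direction: equal, opposite, collinear
  pa <- c(100, -200, 50)
  pb <- pa + 5200 * c(1, 2, 2) / 3
  rs <- sf_forces(sf, pa, pb, p)
  expect_gt(rs$tension, 0)
  expect_equal(rs$force_a, -rs$force_b)
  expect_equal(rs$force_a / sqrt(sum(rs$force_a^2)), c(1, 2, 2) / 3)
  # worked chain: N_sf = 5, L_a0 = 480, d = 3000 -> ~1.129e4 pN
  sf5 <- mechanocell:::new_stress_fiber("ventral", 1, 2, 4000, p)
  sf5$N_sf <- 5L
  sf5$L_a0 <- 480
  sf5$phase <- "motor"
  r5 <- sf_forces(sf5, c(0, 0, 0), c(3000, 0, 0), p)
  k_unit <- sf_unit_stiffness(480, p)
  expect_equal(k_unit, 94.08, tolerance = 1e-2)
  expect_equal(r5$tension, k_unit / 5 * (3000 - 2400))
  expect_equal(r5$tension, 1.129e4, tolerance = 1e-3)
  expect_error(sf_forces(sf, pa, pa, p), "degenerate")
})

test_that("the lifecycle clock walks polymerizing -> motor -> depoly -> out", {
  p <- sf_params(t_poly = 2, t_depoly = 1)
  sf <- mechanocell:::new_stress_fiber("nuclear", 1, 2, 4000, p)
  # not connected: waits in polymerization
  sf1 <- update_phase(sf, 3, fa_alive = TRUE, connected = FALSE, p = p)
  expect_identical(sf1$phase, "polymerizing")
  # connected: promotes to motor after t_poly
  sf2 <- update_phase(sf, 3, fa_alive = TRUE, connected = TRUE, p = p)
  expect_identical(sf2$phase, "motor")
  expect_equal(sf2$phase_clock, 0)
  # FA death during polymerization kills the fiber
  sf3 <- update_phase(sf, 1, fa_alive = FALSE, p = p)
  expect_identical(sf3$phase, "expired")
  # FA death during motor: immediate depolymerization, duration recorded
  sf4 <- sf2
  sf4$phase_clock <- 7
  sf4 <- update_phase(sf4, 0.5, fa_alive = FALSE, p = p)
  expect_identical(sf4$phase, "depolymerizing")
  expect_equal(sf4$motor_duration, 7.5)
  # floor alone does not end the motor phase before 16 s
  sf5 <- sf2
  sf5$L_a0 <- 0.6 * sf5$L_init
  sf5$phase_clock <- 10
  sf5 <- update_phase(sf5, 0.5, fa_alive = TRUE, p = p)
  expect_identical(sf5$phase, "motor")
  sf5$phase_clock <- 16
  sf5 <- update_phase(sf5, 0.5, fa_alive = TRUE, p = p)
  expect_identical(sf5$phase, "depolymerizing")
  # depolymerization expires after t_depoly
  sf6 <- update_phase(sf5, 1.01, fa_alive = TRUE, p = p)
  expect_identical(sf6$phase, "expired")
})

test_that("an unloaded motor phase lasts 16 s plus one step", {
  p <- sf_params()
  sf <- mechanocell:::new_stress_fiber("nuclear", 1, 2, 4000, p)
  sf$phase <- "motor"
  dt <- 0.01
  n <- 0
  while (sf$phase == "motor") {
    sf <- advance_contraction(sf, 0, dt, p)
    sf <- update_phase(sf, dt, fa_alive = TRUE, p = p)
    n <- n + 1
  }
  expect_equal(n * dt, 16, tolerance = 2 * dt)
  expect_equal(sf$motor_duration, 16, tolerance = 2 * dt)
})
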