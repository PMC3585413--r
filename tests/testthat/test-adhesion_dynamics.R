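test_that("binding probability follows 1 - exp(-k_f n_L dt)", {
  expect_equal(binding_probability(0, 0.01), 0)
  expect_equal(binding_probability(100, 0.01), 1 - exp(-1))
  expect_equal(binding_probability(100, 1e6), 1)
  # monotone in both arguments
  expect_true(all(diff(binding_probability(0:50, 0.01)) > 0))
  expect_gt(binding_probability(10, 0.02), binding_probability(10, 0.01))
})

test_that("Bell rate is exponential in force with slope x_b / kBT", {
  expect_identical(bell_rate(0), 1)
  kBT <- 1.380649e-2 * 310  # pN nm at 310 K
  expect_equal(kBT, 4.2800, tolerance = 1e-4)
  # unit exponent: F x_b = kBT
  expect_equal(bell_rate(kBT / 0.02), exp(1))
  expect_equal(bell_rate(214.06), exp(1), tolerance = 1e-3)
  # log-linearity
  Fs <- seq(0, 400, by = 40)
  slopes <- diff(log(bell_rate(Fs))) / diff(Fs)
  expect_equal(slopes, rep(0.02 / kBT, length(slopes)))
})

test_that("rupture probability is 1 - exp(-k_off dt), monotone in both", {
  expect_equal(rupture_probability(0, 0.01), 0)
  expect_equal(rupture_probability(1, 0.01), 1 - exp(-0.01))
  expect_equal(rupture_probability(1, 0.01), 0.00995, tolerance = 1e-3)
  expect_true(all(diff(rupture_probability(seq(0, 10, 1), 0.01)) > 0))
  expect_gt(rupture_probability(1, 0.02), rupture_probability(1, 0.01))
})

test_that("bond updates respect eligibility, budget and the frozen root", {
  f <- build_planar_field(extent_um = 4, c_L = 1140)
  st <- integrin_state(1L)
  proj <- project_node(c(0, 0, 100), c(0, 0, -1), f)
  # near-certain binding (P_b = 1 - e^-13.9) with a rare rupture draw:
  # the first bond freezes the root and takes a ligand from the pool
  set.seed(1)  # draws 0.266 (< P_b: bind) then 0.372 (> P_r = 0.049: keep)
  r <- update_bonds(st, proj, f, bond_force = 0, dt = 0.05)
  expect_identical(r$state$n_b, 1L)
  expect_equal(r$state$root, proj$root)
  expect_identical(r$field$free[proj$triangle_id],
                   f$init[proj$triangle_id] - 1L)
  # ineligible node with no bonds: untouched
  proj_far <- project_node(c(0, 0, 400), c(0, 0, -1), f)
  r2 <- update_bonds(integrin_state(2L), proj_far, f, 0, 0.01)
  expect_identical(r2$state$n_b, 0L)
  expect_identical(r2$field$free, f$free)
  # budget cap
  st3 <- r$state
  st3$n_b <- st3$receptor_budget
  f3 <- r$field
  set.seed(2)
  r3 <- update_bonds(st3, proj, f3, bond_force = 0, dt = 1e6)
  expect_lte(r3$state$n_b, st3$receptor_budget)
})

test_that("single-step binding frequency matches the binomial oracle", {
  f <- build_planar_field(extent_um = 4, c_L = 1140)
  proj <- project_node(c(0, 0, 100), c(0, 0, -1), f)
  # 357 free ligands at dt = 1 ms give P_b ~ 0.3 while the same-step rupture
  # test fires with only P_r ~ 1e-3; the surviving-bond frequency over many
  # single-step trials is P_b (1 - P_r)
  dt <- 1e-3
  f$free[] <- 357L
  p_b <- binding_probability(357, dt)
  expect_equal(p_b, 0.3, tolerance = 2e-3)
  p_keep <- p_b * (1 - rupture_probability(bell_rate(0), dt))
  n_trials <- 10000
  set.seed(99)
  hits <- 0L
  for (i in seq_len(n_trials)) {
    r <- update_bonds(integrin_state(1L), proj, f, 0, dt)
    hits <- hits + r$state$n_b
  }
  se <- sqrt(p_keep * (1 - p_keep) / n_trials)
  expect_lt(abs(hits / n_trials - p_keep), 3 * se)
})

test_that("ligand pools are conserved under arbitrary event sequences", {
  f <- build_planar_field(extent_um = 4, c_L = 200)
  states <- lapply(1:20, integrin_state)
  pos <- cbind(runif(20, -1500, 1500), runif(20, -1500, 1500), 50)
  projs <- lapply(1:20, function(i) project_node(pos[i, ], c(0, 0, -1), f))
  set.seed(7)
  for (step in 1:500) {
    for (i in 1:20) {
      r <- update_bonds(states[[i]], projs[[i]], f,
                        bond_force = runif(1, 0, 50) * states[[i]]$n_b,
                        dt = 0.05)
      states[[i]] <- r$state
      f <- r$field
    }
  }
  bound <- integer(length(f$free))
  for (st in states) {
    if (st$n_b > 0) bound[st$bond_triangle] <- bound[st$bond_triangle] + st$n_b
  }
  expect_identical(f$free + bound, f$init)
  expect_true(all(f$free >= 0L))
  expect_true(all(vapply(states, function(s) s$n_b >= 0L, logical(1))))
})

test_that("mean FA lifetime matches the birth-death master-equation oracle", {
  # small chain: budget 5 receptors, constant per-bond force, pool reset to a
  # fixed free count before every step so the rates are state-independent
  budget <- 5L
  free_fix <- 2L
  dt <- 0.05
  F0 <- 60  # per-bond force, pN
  f <- build_planar_field(extent_um = 2, c_L = 10)
  proj <- project_node(c(0, 0, 100), c(0, 0, -1), f)
  p_b <- binding_probability(free_fix, dt)
  # transition matrix of the in-code order: binding test first, then one
  # rupture test whose per-bond force is bond_force / (post-binding count),
  # with bond_force = F0 * (pre-step count)
  S <- budget + 1L  # states 0..budget
  P <- matrix(0, S, S)
  P[1, 1] <- 1  # absorbed at n_b = 0
  for (n in 1:budget) {
    up <- if (n < budget) p_b else 0
    r_up <- rupture_probability(bell_rate(F0 * n / (n + 1)), dt)
    r0 <- rupture_probability(bell_rate(F0), dt)
    if (n < budget) {
      P[n + 1, n + 2] <- up * (1 - r_up)
      P[n + 1, n + 1] <- P[n + 1, n + 1] + up * r_up
    }
    P[n + 1, n + 1] <- P[n + 1, n + 1] + (1 - up) * (1 - r0)
    P[n + 1, n] <- P[n + 1, n] + (1 - up) * r0
  }
  Q <- P[-1, -1, drop = FALSE]
  exp_steps <- solve(diag(budget) - Q, rep(1, budget))  # from state n = 1..
  oracle_mean_steps <- exp_steps[1]
  # simulate the same chain through update_bonds
  set.seed(11)
  n_rep <- 1500
  steps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    st <- integrin_state(1L, receptor_budget = budget)
    st$n_b <- 1L
    st$root <- proj$root
    st$bond_triangle <- proj$triangle_id
    k <- 0
    while (st$n_b > 0L && k < 20000) {
      f$free[] <- free_fix
      out <- update_bonds(st, proj, f, bond_force = F0 * st$n_b, dt = dt)
      st <- out$state
      k <- k + 1
    }
    steps[r] <- k
  }
  se <- sd(steps) / sqrt(n_rep)
  expect_lt(abs(mean(steps) - oracle_mean_steps), 4 * se)
})

test_that("focal adhesion force is a tether toward the frozen root", {
  st <- integrin_state(1L)
  expect_equal(focal_adhesion_force(c(0, 0, 100), st), c(0, 0, 0))
  st$n_b <- 10L
  st$root <- c(0, 0, 0)
  st$bond_triangle <- 1L
  # at the equilibrium distance: zero force
  expect_equal(focal_adhesion_force(c(0, 0, 30), st), c(0, 0, 0))
  # compressed: zero force (no pushing)
  expect_equal(focal_adhesion_force(c(0, 0, 10), st), c(0, 0, 0))
  # 10 bonds, 1 pN/nm, L_b = 35 nm -> 50 pN toward the root
  Fv <- focal_adhesion_force(c(0, 0, 35), st)
  expect_equal(Fv, c(0, 0, -50))
  # tilted bond produces in-plane traction
  Fv2 <- focal_adhesion_force(c(40, 0, 30), st)
  expect_lt(Fv2[1], 0)
  expect_equal(sqrt(sum(Fv2^2)), 10 * (sqrt(40^2 + 30^2) - 30))
})
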