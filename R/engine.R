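#' Simulation configuration
#'
#' Collects every parameter block of the model into one flat list. Defaults
#' are the standard parameter set: membrane stiffness and friction from
#' [elastic_params], adhesion kinetics (forward rate 1 per molecule per s,
#' unstressed off-rate 1/s, Bell transition distance 0.02 nm, bond spring
#' 1 pN/nm, integrin equilibrium distance 30 nm, critical height 300 nm,
#' 300 receptors per node), stress-fiber parameters from [sf_params],
#' 300 pN lamellipodium force, and the numerics (adaptive dt in
#' [1e-3, 1e-2] s, local-error tolerance 1e-4 um = 0.1 nm per step).
#'
#' @param duration simulated time, s
#' @param seed RNG seed (all stochastic draws come from one R RNG stream)
#' @param c_L ligand surface density, molecules/um^2 (planar scenarios)
#' @param shape micropattern shape for spreading scenarios
#' @param frame_interval frame emission interval, s (default 15)
#' @param radius_um,node_count,nucleus_ratio,gap_nm mesh geometry
#'   (see [build_cell_meshes])
#' @param extent_um planar field side (default 60; large enough for a few
#'   hours of migration from the center)
#' @param ep an [elastic_params] block
#' @param sp an [sf_params] block
#' @param receptor_budget integrins per node (default 300)
#' @param k_f,k_off0,x_b_nm,temperature_K,k_b,lambda_nm,h_c_nm adhesion
#'   kinetics and mechanics
#' @param F_L_pN lamellipodium force per leading node (default 300)
#' @param pol_interval_s,pol_sigma_deg,pol_min_disp_nm polarity update rule
#' @param dt_min,dt_max,convergence_tol integrator controls (tolerance in um)
#' @param compat_interval_steps steps between nucleus-in-cell compatibility
#'   sweeps (substrate penetration is corrected every step)
#' @param nuclear_sf_enabled set `FALSE` for the nucleus-disconnected variant
#' @param pattern_diameter_um,wedge_deg,arc_thickness_um,bar_length_um,bar_width_um
#'   micropattern dimensions (see [build_micropattern_field])
#' @return list of class `sim_config`
#' @export
sim_config <- function(duration = 3600, seed = 1, c_L = 1140,
                       shape = "disk", frame_interval = 15,
                       radius_um = 8, node_count = 549, nucleus_ratio = 0.45,
                       gap_nm = 30, extent_um = 60,
                       ep = elastic_params(), sp = sf_params(),
                       receptor_budget = 300L, k_f = 1, k_off0 = 1,
                       x_b_nm = 0.02, temperature_K = 310, k_b = 1,
                       lambda_nm = 30, h_c_nm = 300, F_L_pN = 300,
                       pol_interval_s = 300, pol_sigma_deg = 10,
                       pol_min_disp_nm = 10, dt_min = 1e-3, dt_max = 1e-2,
                       convergence_tol = 1e-4, compat_interval_steps = 10L,
                       nuclear_sf_enabled = TRUE, pattern_diameter_um = 6,
                       wedge_deg = 90, arc_thickness_um = 2,
                       bar_length_um = 4, bar_width_um = 2) {
  stopifnot(duration > 0, dt_min <= dt_max, dt_min > 0)
  structure(as.list(environment()), class = "sim_config")
}

cfg_to_cpp <- function(cfg, field, migration_mode) {
  list(
    duration = cfg$duration, frame_interval = cfg$frame_interval,
    dt_min = cfg$dt_min, dt_max = cfg$dt_max,
    tol_nm = cfg$convergence_tol * 1000,
    k_c_line = cfg$ep$k_c_line, k_c_area = cfg$ep$k_c_area,
    k_n_line = cfg$ep$k_n_line, k_n_area = cfg$ep$k_n_area,
    C_c = cfg$ep$C_c, C_n = cfg$ep$C_n,
    k_b = cfg$k_b, lambda = cfg$lambda_nm, h_c = cfg$h_c_nm,
    k_f = cfg$k_f, k_off0 = cfg$k_off0, x_b = cfg$x_b_nm,
    kBT = KB_PN_NM * cfg$temperature_K,
    receptor_budget = as.integer(cfg$receptor_budget),
    E_SF = cfg$sp$E_SF, A_SF = cfg$sp$A_SF, v_m0 = cfg$sp$v_m0,
    F_m = cfg$sp$F_m, hill_a = cfg$sp$hill_a,
    t_poly = cfg$sp$t_poly, t_depoly = cfg$sp$t_depoly,
    contraction_floor = cfg$sp$contraction_floor, L_init = cfg$sp$L_init,
    motor_min_s = cfg$sp$motor_min_s, ventral_prob = cfg$sp$ventral_prob,
    ventral_angle_deg = cfg$sp$ventral_angle_deg,
    ventral_min_um = cfg$sp$ventral_min_um,
    ventral_max_um = cfg$sp$ventral_max_um,
    F_L = cfg$F_L_pN, pol_interval = cfg$pol_interval_s,
    pol_sigma_deg = cfg$pol_sigma_deg,
    pol_min_disp_nm = cfg$pol_min_disp_nm,
    migration_mode = as.integer(migration_mode),
    compat_interval_steps = as.integer(cfg$compat_interval_steps),
    nuclear_sf_enabled = as.integer(isTRUE(cfg$nuclear_sf_enabled)),
    field_nx = field$nx, field_ny = field$ny,
    field_x0 = field$x0, field_y0 = field$y0,
    field_dx = field$dx, field_dy = field$dy
  )
}

#' Run a full cell simulation
#'
#' Initializes the scenario, advances the overdamped mechanochemical dynamics
#' until `cfg$duration`, and returns the trajectory archive. Scenarios:
#' \describe{
#'   \item{migration}{planar substrate at density `cfg$c_L`, polarized
#'     protrusion with noisy persistence.}
#'   \item{spreading}{micropattern `cfg$shape` at density `cfg$c_L`
#'     (475 molecules/um^2 is the standard spreading density), isotropic
#'     rim protrusion.}
#'   \item{nucleus_disconnected}{migration with nucleus-connected stress
#'     fibers disabled (ventral fibers only).}
#' }
#' The same seed and configuration give a bit-identical trajectory.
#'
#' @param cfg a [sim_config]
#' @param scenario one of "migration", "spreading", "nucleus_disconnected"
#' @return a `cell_trajectory`: list with `frames` (per-frame data frame:
#'   time, nucleus/cell centroid, contact area, traction stress, bond and
#'   fiber counts), `sf_log` (completed motor phases), final mesh state,
#'   ligand audit vectors, and integrator diagnostics
#' @export
simulate_cell <- function(cfg, scenario = c("migration", "spreading",
                                            "nucleus_disconnected")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(cfg, "sim_config"))
  if (scenario == "nucleus_disconnected") cfg$nuclear_sf_enabled <- FALSE
  migration_mode <- scenario != "spreading"
  field <- if (scenario == "spreading") {
    build_micropattern_field(cfg$shape, c_L = cfg$c_L,
                             diameter_um = cfg$pattern_diameter_um,
                             wedge_deg = cfg$wedge_deg,
                             arc_thickness_um = cfg$arc_thickness_um,
                             bar_length_um = cfg$bar_length_um,
                             bar_width_um = cfg$bar_width_um)
  } else {
    build_planar_field(cfg$extent_um, cfg$c_L)
  }
  meshes <- build_cell_meshes(cfg$radius_um, cfg$node_count,
                              cfg$nucleus_ratio, cfg$gap_nm)
  set.seed(cfg$seed)
  res <- run_sim_cpp(
    meshes$cell$pos, meshes$cell$edges - 1L, meshes$cell$tris - 1L,
    meshes$cell$ref_edge_lengths, meshes$cell$ref_tri_areas,
    meshes$nucleus$pos, meshes$nucleus$edges - 1L, meshes$nucleus$tris - 1L,
    meshes$nucleus$ref_edge_lengths, meshes$nucleus$ref_tri_areas,
    field$verts, field$tris - 1L, as.integer(field$mask), field$init,
    field$area, cfg_to_cpp(cfg, field, migration_mode))
  cell <- meshes$cell
  cell$pos <- res$cell_pos
  cell <- update_differentials(cell)
  nucleus <- meshes$nucleus
  nucleus$pos <- res$nucleus_pos
  nucleus <- update_differentials(nucleus)
  structure(list(
    scenario = scenario, config = cfg,
    frames = as.data.frame(res$frames),
    sf_log = as.data.frame(res$sf_log),
    cell = cell, nucleus = nucleus,
    n_b = res$n_b, fa_force_pN = res$fa_force_pN,
    fa_tangential_pN = res$fa_tangential_pN,
    ligand_free = res$ligand_free, ligand_bound = res$ligand_bound,
    ligand_init = field$init, polarity = res$polarity,
    diag = res$diag
  ), class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  fr <- x$frames
  cat(sprintf("cell_trajectory (%s): %.0f s simulated, %d frames\n",
              x$scenario, max(fr$t), nrow(fr)))
  cat(sprintf("  final: %d FAs (%d bonds), contact %.1f um^2, traction %.2f Pa\n",
              fr$n_fa[nrow(fr)], fr$n_bonds[nrow(fr)],
              fr$contact_area_um2[nrow(fr)], fr$traction_Pa[nrow(fr)]))
  cat(sprintf("  %d completed motor phases; %d steps (mean dt %.2g s)\n",
              nrow(x$sf_log), as.integer(x$diag$n_steps),
              x$diag$dt_mean_accepted))
  invisible(x)
}

#' Assemble the per-node force balance of a small explicit state
#'
#' Composes the quasi-static force sum at every node from the module-level
#' pieces: cortical nodes receive focal adhesion + elastic + stress-fiber +
#' lamellipodium forces, nuclear nodes elastic + stress-fiber forces (drag is
#' supplied by the integrator). Intended for small, explicitly built states;
#' the simulation engine carries its own fused implementation of the same
#' sum.
#'
#' @param cell,nucleus [tri_mesh] objects with current differentials
#' @param fa_states list of [integrin_state] (any subset of nodes)
#' @param sfs list of `stress_fiber` objects (motor-phase fibers exert force)
#' @param leading leading-edge node ids
#' @param ep an [elastic_params]
#' @param sp an [sf_params]
#' @return list `cell`, `nucleus` of N x 3 force matrices (pN)
#' @export
assemble_forces <- function(cell, nucleus, fa_states = list(), sfs = list(),
                            leading = integer(0), ep = elastic_params(),
                            sp = sf_params()) {
  Fc <- elastic_forces(cell, ep$k_c_line, ep$k_c_area)
  Fn <- elastic_forces(nucleus, ep$k_n_line, ep$k_n_area)
  for (st in fa_states) {
    Fc[st$node_id, ] <- Fc[st$node_id, ] +
      focal_adhesion_force(cell$pos[st$node_id, ], st)
  }
  for (sf in sfs) {
    if (sf$phase != "motor") next
    pos_b <- if (sf$kind == "nuclear") nucleus$pos[sf$end_b, ]
             else cell$pos[sf$end_b, ]
    fr <- sf_forces(sf, cell$pos[sf$end_a, ], pos_b, sp)
    Fc[sf$end_a, ] <- Fc[sf$end_a, ] + fr$force_a
    if (sf$kind == "nuclear") {
      Fn[sf$end_b, ] <- Fn[sf$end_b, ] + fr$force_b
    } else {
      Fc[sf$end_b, ] <- Fc[sf$end_b, ] + fr$force_b
    }
  }
  if (length(leading)) {
    Fc <- Fc + lamellipodium_forces(leading, cell)
  }
  if (any(!is.finite(Fc)) || any(!is.finite(Fn))) {
    stop("non-finite force in assembled balance")
  }
  list(cell = Fc, nucleus = Fn)
}
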