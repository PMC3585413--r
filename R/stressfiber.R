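#' Stress fibers
#'
#' A stress fiber (SF) is a chain of N_sf sarcomeric contractile compartments,
#' each of unstressed length L_a0 (800 nm at birth). Nucleus-connected SFs
#' span one integrin (cortical) node and the nearest nuclear node; ventral SFs
#' span two FA-bearing integrin nodes aligned with the lower principal
#' direction of the cortical surface strain. The lifecycle is polymerization
#' (180 s, no force), motor activity (contraction at the Hill velocity,
#' tension-only elastic force, ends when the sarcomeres reach the 60% floor
#' after at least 16 s, or when the anchoring FA dissolves), then
#' depolymerization (1 s, during which the node may not nucleate a new
#' adhesion complex).
#'
#' @name stress_fiber
NULL

#' Stress-fiber parameters
#'
#' @param E_SF Young's modulus of an SF, pN/nm^2 (default 0.23 = 230 kPa)
#' @param A_SF cross-sectional area, nm^2 (default pi * 250^2, i.e. the
#'   0.196 um^2 of a 250 nm radius bundle)
#' @param v_m0 unloaded myosin sliding rate, nm/s (default 10)
#' @param F_m stall force, pN (default 5000: a ~0.2 um^2 cross-section fiber
#'   carries nanonewton-scale tension)
#' @param hill_a Hill curvature parameter, pN (default F_m / 4)
#' @param t_poly polymerization time, s (default 180)
#' @param t_depoly depolymerization time, s (default 1)
#' @param contraction_floor minimum L_a0 as a fraction of the initial length
#'   (default 0.6)
#' @param L_init initial sarcomere length, nm (default 800)
#' @param motor_min_s minimum motor-phase duration before the floor can end
#'   it, s (default 16 = time to contract 800 -> 480 nm at both-ends sliding)
#' @param ventral_prob probability that a new FA attempts ventral SF
#'   nucleation (default 0.3)
#' @param ventral_angle_deg alignment tolerance to the lower principal strain
#'   direction (default 20)
#' @param ventral_min_um,ventral_max_um ventral SF length window (default
#'   2-40 um)
#' @return list of class `sf_params`
#' @export
sf_params <- function(E_SF = 0.23, A_SF = pi * 250^2, v_m0 = 10, F_m = 5000,
                      hill_a = F_m / 4, t_poly = 180, t_depoly = 1,
                      contraction_floor = 0.6, L_init = 800, motor_min_s = 16,
                      ventral_prob = 0.3, ventral_angle_deg = 20,
                      ventral_min_um = 2, ventral_max_um = 40) {
  stopifnot(E_SF > 0, A_SF > 0, v_m0 > 0, F_m > 0, hill_a > 0,
            t_poly >= 0, t_depoly > 0,
            contraction_floor > 0, contraction_floor < 1)
  structure(as.list(environment()), class = "sf_params")
}

new_stress_fiber <- function(kind, end_a, end_b, dist_nm, p = sf_params()) {
  structure(list(kind = kind, end_a = end_a, end_b = end_b,
                 N_sf = max(1L, as.integer(round(dist_nm / p$L_init))),
                 L_a0 = p$L_init, L_init = p$L_init,
                 phase = "polymerizing", phase_clock = 0),
            class = "stress_fiber")
}

#' Nucleate a nucleus-connected stress fiber
#'
#' The nuclear endpoint is the nucleus node nearest to the integrin node
#' (ties broken by lowest node id); the compartment count is the distance in
#' 800 nm sarcomere units, floored at 1.
#'
#' @param integrin_node cortical node id (must carry a live FA)
#' @param integrin_pos its position, nm
#' @param nucleus nucleus [tri_mesh]
#' @param p [sf_params]
#' @return a `stress_fiber` in the polymerizing phase
#' @export
nucleate_nuclear_sf <- function(integrin_node, integrin_pos, nucleus,
                                p = sf_params()) {
  d2 <- rowSums((nucleus$pos -
                   matrix(integrin_pos, nrow(nucleus$pos), 3, byrow = TRUE))^2)
  j <- which.min(d2)                      # which.min takes the first = lowest id
  new_stress_fiber("nuclear", integrin_node, j, sqrt(d2[j]), p)
}

#' Nucleate a ventral stress fiber
#'
#' Searches the other FA-bearing nodes for a partner whose direction from the
#' seed node lies within the angular tolerance of the node's lower principal
#' strain direction (either sense) and whose distance falls in the length
#' window; the best-aligned candidate wins. Returns `NULL` when no candidate
#' qualifies.
#'
#' @param integrin_node seed node id
#' @param cell cell [tri_mesh]
#' @param dir_min lower principal strain direction at the seed node (3-vector)
#' @param fa_nodes ids of other nodes with live FAs
#' @param p [sf_params]
#' @return a `stress_fiber` or `NULL`
#' @export
nucleate_ventral_sf <- function(integrin_node, cell, dir_min, fa_nodes,
                                p = sf_params()) {
  fa_nodes <- setdiff(fa_nodes, integrin_node)
  if (!length(fa_nodes)) return(NULL)
  x0 <- cell$pos[integrin_node, ]
  best <- NULL; best_cos <- cos(p$ventral_angle_deg * pi / 180)
  for (k in fa_nodes) {
    v <- cell$pos[k, ] - x0
    d <- sqrt(sum(v^2))
    if (d < p$ventral_min_um * 1000 || d > p$ventral_max_um * 1000) next
    ca <- abs(sum(v * dir_min)) / (d * sqrt(sum(dir_min^2)))
    if (ca >= best_cos) {
      best_cos <- ca
      best <- list(k = k, d = d)
    }
  }
  if (is.null(best)) return(NULL)
  new_stress_fiber("ventral", integrin_node, best$k, best$d, p)
}

#' Stiffness of a single sarcomere compartment
#'
#' k'_unit = E_SF A_SF / L_a: stiffer as the compartment shortens.
#'
#' @param L_a compartment length, nm
#' @param p [sf_params]
#' @return stiffness, pN/nm
#' @export
sf_unit_stiffness <- function(L_a, p = sf_params()) {
  stopifnot(all(L_a > 0))
  p$E_SF * p$A_SF / L_a
}

#' Hill force-velocity relation for myosin sliding
#'
#' v_m = v_m0 (1 - F/F_m) / (1 + F/a): the unloaded rate (10 nm/s) falls
#' monotonically to zero at the stall force; loads at or beyond stall give
#' zero (no lengthening is modeled).
#'
#' @param F axial load, pN (>= 0)
#' @param p [sf_params]
#' @return sliding velocity, nm/s
#' @export
hill_velocity <- function(F, p = sf_params()) {
  stopifnot(all(F >= 0))
  v <- p$v_m0 * (1 - F / p$F_m) / (1 + F / p$hill_a)
  pmax(0, v)
}

#' Advance sarcomere contraction over one step
#'
#' Both ends of each compartment slide, so the unstressed length shortens at
#' twice the Hill velocity: L_a0 <- max(floor, L_a0 - 2 v_m(F) dt). Unloaded,
#' the 800 -> 480 nm (60% of initial) contraction takes exactly 16 s.
#'
#' @param sf a `stress_fiber` in the motor phase
#' @param F_axial current axial tension, pN
#' @param dt time step, s
#' @param p [sf_params]
#' @return the updated fiber
#' @export
advance_contraction <- function(sf, F_axial, dt, p = sf_params()) {
  stopifnot(sf$phase == "motor")
  floor_nm <- p$contraction_floor * sf$L_init
  sf$L_a0 <- max(floor_nm, sf$L_a0 - 2 * hill_velocity(F_axial, p) * dt)
  sf
}

#' Tension-only force pair exerted by a stress fiber
#'
#' The fiber is a chain of N_sf compartments: rest length N_sf L_a0, chain
#' stiffness k'_unit / N_sf. Tension K (d - R), clamped at zero for d < R
#' (fibers buckle rather than push), pulls the endpoints together: equal and
#' opposite forces along the fiber axis.
#'
#' @param sf a `stress_fiber`
#' @param pos_a,pos_b endpoint positions, nm
#' @param p [sf_params]
#' @return list `force_a`, `force_b` (pN 3-vectors) and `tension` (pN)
#' @export
sf_forces <- function(sf, pos_a, pos_b, p = sf_params()) {
  v <- pos_b - pos_a
  d <- sqrt(sum(v^2))
  if (d == 0) stop("degenerate stress fiber: coincident endpoints")
  rest <- sf$N_sf * sf$L_a0
  K <- sf_unit_stiffness(sf$L_a0, p) / sf$N_sf
  tension <- max(0, K * (d - rest))
  fa <- tension * v / d
  list(force_a = fa, force_b = -fa, tension = tension)
}

#' Advance the lifecycle phase of a stress fiber
#'
#' polymerizing -> motor after t_poly (only if the fiber is connected and the
#' anchoring FA is alive, otherwise the fiber expires); motor ->
#' depolymerizing when the sarcomeres sit at the contraction floor with at
#' least `motor_min_s` of motor time, or immediately when the FA dissolves;
#' depolymerizing -> expired after t_depoly. The motor-phase duration is
#' recorded in `motor_duration` on exit from the motor phase.
#'
#' @param sf a `stress_fiber`
#' @param dt time step, s
#' @param fa_alive is the anchoring FA (both FAs, for ventral fibers) alive?
#' @param connected is the far end attached (nucleus reached / partner FA)?
#' @param p [sf_params]
#' @return the updated fiber; `sf$phase == "expired"` when fully disassembled
#' @export
update_phase <- function(sf, dt, fa_alive, connected = TRUE,
                         p = sf_params()) {
  sf$phase_clock <- sf$phase_clock + dt
  if (sf$phase == "polymerizing") {
    if (!fa_alive) {
      sf$phase <- "expired"
    } else if (sf$phase_clock >= p$t_poly && connected) {
      sf$phase <- "motor"
      sf$phase_clock <- 0
    }
  } else if (sf$phase == "motor") {
    at_floor <- sf$L_a0 <= p$contraction_floor * sf$L_init + 1e-9
    if (!fa_alive || (at_floor && sf$phase_clock >= p$motor_min_s)) {
      sf$motor_duration <- sf$phase_clock
      sf$phase <- "depolymerizing"
      sf$phase_clock <- 0
    }
  } else if (sf$phase == "depolymerizing") {
    if (sf$phase_clock >= p$t_depoly) sf$phase <- "expired"
  }
  sf
}
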