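#' Focal adhesion stochastic dynamics
#'
#' Each cortical node carries a budget of integrin receptors (300 by default,
#' i.e. 164,700 integrins spread over 549 nodes). Ligand-receptor bonds form
#' and rupture by a per-node Monte Carlo process: one binding test and one
#' rupture test per node per time step, with event probabilities
#' `1 - exp(-rate * dt)` that stay well below 1 at dt <= 0.01 s. Rupture
#' follows Bell's slip-bond law. A focal adhesion (FA) is the bundle of bonds
#' at a node; its root on the substrate is frozen when the first bond forms
#' and cleared when the last bond breaks, so tangential motion of the node
#' tilts the bond and generates in-plane traction.
#'
#' @name adhesion
NULL

# Boltzmann constant in pN nm / K
KB_PN_NM <- 1.380649e-2

#' Per-node integrin state
#'
#' @param node_id cortical node index
#' @param receptor_budget integrins available at this node (default 300)
#' @return an `integrin_state` list: `n_b` current bonds, `root` bond anchor
#'   (nm, fixed while the FA lives), `bond_triangle` ligand triangle id,
#'   `fa_age` seconds since FA formation, `eligible` flag
#' @export
integrin_state <- function(node_id, receptor_budget = 300L) {
  structure(list(node_id = node_id,
                 receptor_budget = as.integer(receptor_budget),
                 n_b = 0L, root = NULL, bond_triangle = NA_integer_,
                 fa_age = 0, eligible = FALSE),
            class = "integrin_state")
}

#' Single-receptor binding probability over a time step
#'
#' The association rate is k_on = k_f * n_free, with k_f the forward reaction
#' rate (1 per molecule per second) and n_free the number of unbound ligands
#' on the substrate triangle under the node; the binding probability over dt
#' is 1 - exp(-k_on dt).
#'
#' @param free_ligands unbound ligand count on the local substrate triangle
#' @param dt time step, s
#' @param k_f forward reaction rate, molecule^-1 s^-1 (default 1)
#' @return probability in [0, 1]
#' @export
binding_probability <- function(free_ligands, dt, k_f = 1) {
  stopifnot(all(free_ligands >= 0), dt > 0)
  1 - exp(-k_f * free_ligands * dt)
}

#' Bell slip-bond dissociation rate
#'
#' k_off = k_off0 * exp(F x_b / kB T): the unstressed dissociation rate
#' (1 s^-1) grows exponentially with the force per bond, with transition
#' distance x_b = 0.02 nm.
#'
#' @param F_per_bond force on a single bond, pN
#' @param temperature_K absolute temperature (default 310)
#' @param k_off0 unstressed dissociation rate, s^-1 (default 1)
#' @param x_b transition distance, nm (default 0.02)
#' @return dissociation rate, s^-1
#' @export
bell_rate <- function(F_per_bond, temperature_K = 310, k_off0 = 1,
                      x_b = 0.02) {
  stopifnot(all(F_per_bond >= 0))
  k_off0 * exp(F_per_bond * x_b / (KB_PN_NM * temperature_K))
}

#' Bond rupture probability over a time step
#'
#' @param k_off dissociation rate, s^-1
#' @param dt time step, s
#' @return probability in [0, 1]
#' @export
rupture_probability <- function(k_off, dt) {
  stopifnot(all(k_off >= 0), dt > 0)
  1 - exp(-k_off * dt)
}

#' Monte Carlo update of the bonds at one integrin node
#'
#' Performs the per-step stochastic bookkeeping: if the node is eligible and
#' has spare receptors, one binding test against the free-ligand pool of the
#' projected substrate triangle (`P_ran1 < P_b` adds a bond and takes a ligand
#' from the pool; the first bond fixes the FA root at the projection hit
#' point). If bonds exist, one rupture test at the Bell rate for the current
#' per-bond force (`P_ran2 < P_r` releases a bond and returns its ligand).
#' When the last bond breaks the FA dissolves and the root is cleared. Tests
#' continue every subsequent step until the bond breaks completely.
#'
#' @param state an [integrin_state]
#' @param projection result of [project_node] for this node at this step
#' @param field the [ligand_field] (its free pool is updated)
#' @param bond_force magnitude of the total FA force on the node, pN
#' @param dt time step, s
#' @param k_f,temperature_K kinetic parameters
#' @return list `state`, `field`
#' @export
update_bonds <- function(state, projection, field, bond_force, dt,
                         k_f = 1, temperature_K = 310) {
  state$eligible <- isTRUE(projection$eligible)
  if (state$eligible && state$n_b < state$receptor_budget) {
    tid <- if (state$n_b > 0L) state$bond_triangle else projection$triangle_id
    nfree <- field$free[tid]
    if (nfree > 0L) {
      p_b <- binding_probability(nfree, dt, k_f)
      if (stats::runif(1) < p_b) {
        if (state$n_b == 0L) {
          state$root <- projection$root
          state$bond_triangle <- projection$triangle_id
          state$fa_age <- 0
        }
        state$n_b <- state$n_b + 1L
        field$free[state$bond_triangle] <- field$free[state$bond_triangle] - 1L
      }
    }
  }
  if (state$n_b > 0L) {
    per_bond <- bond_force / state$n_b
    p_r <- rupture_probability(bell_rate(per_bond, temperature_K), dt)
    if (stats::runif(1) < p_r) {
      field$free[state$bond_triangle] <- field$free[state$bond_triangle] + 1L
      state$n_b <- state$n_b - 1L
      if (state$n_b == 0L) {
        state$root <- NULL
        state$bond_triangle <- NA_integer_
        state$fa_age <- 0
      }
    }
    state$fa_age <- state$fa_age + dt
  }
  list(state = state, field = field)
}

#' Focal adhesion force on a node
#'
#' The FA acts as n_b parallel springs of stiffness k_b (~1 pN/nm each)
#' anchored at the frozen root x_L: magnitude n_b k_b (L_b - lambda) for bond
#' length L_b beyond the integrin equilibrium distance lambda = 30 nm,
#' directed from the node toward the root. Compressed bonds (L_b < lambda)
#' transmit no force (bonds are tethers, not struts).
#'
#' @param node_pos node position, nm
#' @param state an [integrin_state]
#' @param k_b single-bond spring constant, pN/nm (default 1)
#' @param lambda_nm integrin equilibrium distance, nm (default 30)
#' @return force 3-vector, pN
#' @export
focal_adhesion_force <- function(node_pos, state, k_b = 1, lambda_nm = 30) {
  if (state$n_b == 0L || is.null(state$root)) return(c(0, 0, 0))
  dvec <- state$root - node_pos
  L_b <- sqrt(sum(dvec^2))
  if (L_b <= lambda_nm) return(c(0, 0, 0))
  state$n_b * k_b * (L_b - lambda_nm) * dvec / L_b
}
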