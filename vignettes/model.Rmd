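---
title: "The mechanochemical cell model: assumptions, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechanochemical cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mechanocell` simulates one adherent animal cell as two closed triangulated
elastic membranes — a cortical (cell) membrane and a nuclear membrane, 549
nodes each by default — interacting with a planar, ligand-coated substrate.
Four force systems act on the cortical nodes and two on the nuclear nodes:

* **Membrane elasticity.** Each mesh stores relaxed edge lengths $L_{i0}$ and
  triangle areas $A_{i0}$ frozen at build time. The stored energy is
  $E = \tfrac{k_l}{2}\sum_i (L_i - L_{i0})^2 +
       \tfrac{k_a}{2}\sum_i (A_i - A_{i0})^2 / A_{i0}$,
  and nodal forces are its exact analytic negative gradient. Spring
  constants (cell line $5\times10^{-5}$ N/m, nucleus line $5\times10^{-3}$
  N/m, areas $10^{-4}$ N/m) are the standard spring-network values for red
  cell and nucleus meshes. The exact quadratic form of the published energy
  is not recoverable from the source we reimplemented (the equations are
  images), so the harmonic extension form is used for edges and the
  $A_0$-normalized quadratic for areas — the unique convex quadratics that
  keep the tabulated constants dimensionally consistent. No bending or
  volume term is included.

* **Focal adhesions (FAs).** Each cortical node carries 300 integrin
  receptors (164,700 over the cell). Per time step each node runs one
  binding test, $P_b = 1 - e^{-k_f n_L \Delta t}$ against the free-ligand
  pool $n_L$ of the substrate triangle under it ($k_f = 1$
  molecule$^{-1}$s$^{-1}$), and one rupture test,
  $P_r = 1 - e^{-k_{off}\Delta t}$ with the Bell slip-bond rate
  $k_{off} = k_{off}^0 e^{F x_b / k_B T}$ ($k_{off}^0 = 1$ s$^{-1}$,
  $x_b = 0.02$ nm, $T = 310$ K, equal load sharing across the bundle).
  Bonding requires the outward node normal to oppose the substrate normal
  and a gap below $h_c = 300$ nm. The bond root is frozen where the first
  bond forms and cleared when the last one breaks; tangential node motion
  therefore tilts the bundle and produces in-plane traction. The FA force is
  $n_b k_b (L_b - \lambda)$ toward the root ($k_b = 1$ pN/nm,
  $\lambda = 30$ nm), zero under compression (bonds are tethers). Ruptured
  ligands return to the free pool, so free + bound is conserved per
  triangle.

* **Stress fibers (SFs).** Chains of $N_{sf}$ sarcomeric compartments of
  unstressed length $L_{a0}$ (800 nm at birth). Nucleus-connected fibers
  link an FA node to the nearest nuclear node; ventral fibers link two FA
  nodes aligned (within 20°) with the lower principal direction of the
  Green–Lagrange surface strain, within a 2–40 µm window. The lifecycle is
  polymerization (180 s, no force), motor activity, and depolymerization
  (1 s, during which the node cannot seed a new adhesion complex). During
  motor activity the compartments shorten from both ends at the Hill
  velocity $v_m = v_{m0}(1 - F/F_m)/(1 + F/a)$ ($v_{m0} = 10$ nm/s) down to
  a floor of 60% of the initial length; unloaded, that takes exactly 16 s.
  The fiber force is tension-only: stiffness $E_{SF} A_{SF}/(L_{a0}
  N_{sf}^2)$ per unit extension beyond the rest length $N_{sf} L_{a0}$
  ($E_{SF} = 230$ kPa, $A_{SF} = \pi (250\,\mathrm{nm})^2$). The motor
  phase ends at the floor (after ≥ 16 s) or immediately when the anchoring
  FA dissolves; its duration is the fiber "lifetime" used in the
  leading-/trailing-edge statistics.

* **Lamellipodium.** A constant 300 pN per node along the outward in-plane
  normal, applied only at the leading edge: contact-rim nodes (within
  $h_c$ of the substrate, bordering a non-contact neighbor) whose
  projection lies on ligand-coated substrate and — in migration mode —
  whose in-plane normal faces the polarity direction.

* **Drag.** Motion is overdamped and quasi-static: $C\,\dot x = F(x)$ with
  $C = 0.001$ N·s/m per node for both membranes. Drag is the only
  dissipative term; it lumps the energy released by bond rupture and fiber
  turnover.

## Free choices the source does not constrain

Several ingredients are not specified by the published description and are
this package's own design, all exposed in `sim_config()`:

* **Stall force.** Only $v_m(0) = 10$ nm/s and the existence of a stall are
  constrained. We use $F_m = 5000$ pN with Hill curvature $a = F_m/4$. A
  fiber of 0.196 µm² cross-section carries nanonewton tensions in isolated
  stress-fiber measurements — the same literature the Young's modulus comes
  from. A much smaller stall (e.g. hundreds of pN) is reached within a
  second at a quasi-isometric anchor, freezing contraction far from the
  floor and turning the motor-phase lifetime into a pure FA-survival time;
  the nanonewton scale keeps the force-driven bond-rupture mechanism (and
  the ~16–40 s lifetimes) active.
* **Fiber turnover.** The polymerize/contract/disassemble cycle repeats
  while the adhesion persists: an FA-bearing node without a fiber
  re-nucleates one, except while a depolymerizing fiber is still attached.
  Ventral nucleation is attempted with probability 0.3 once per cycle
  (every 180 s) per FA node with a free ventral slot.
* **Polarity and the leading edge.** The published model assumes a leading
  edge but never defines one on a planar substrate. We track a polarity
  unit vector updated every 5 min from the smoothed in-plane nucleus
  displacement, with 10° Gaussian angular noise and a 10 nm minimum
  displacement (below it the direction persists). Spreading scenarios have
  no polarity: protrusion is isotropic along the contact rim. This rule is
  the package's main free modeling choice; it produces sustained
  random-walk migration and is fully seeded.
* **Nucleus radius.** Not stated; default 0.45 × cell radius (3.6 µm), a
  typical nucleus/cell ratio. It only scales nuclear-fiber lengths.
* **Tessellation.** 549 nodes is not a Loop-subdivision count; the builder
  subdivides an icosahedron and splits exactly the number of edges needed
  to land on the requested count, so any $N \ge 12$ is met exactly.
* **Micropattern dimensions.** The published experiments' pattern sizes are
  not reproduced numerically; the sizing rule is that the pattern area
  should be comparable to the model cell's spread contact area so the
  geometry actually constrains adhesion. This model cell free-spreads to
  ~28 µm² of ventral contact, giving defaults of a 6 µm disk, a 90° pacman
  wedge, and a crossbow with 2 µm arc and 4 × 2 µm bar. Absolute
  dimensions scale traction magnitudes, not the qualitative patterns.

## Numerics

* **Integrator.** A linearly implicit scheme: the stiff node-local FA
  spring (up to $n_b k_b = 300$ pN/nm) is integrated exactly
  (exponential update toward the instantaneous equilibrium), all soft
  forces explicitly. Local error is estimated by step doubling and kept
  below the convergence tolerance of $10^{-4}$ µm (0.1 nm) per step; the
  step adapts within $[10^{-3}, 10^{-2}]$ s. At the lower clamp the step is
  accepted: transient bond events that exceed the tolerance there are
  physically benign and self-limit. Non-finite forces abort the run.
* **Event schedule.** Per accepted step: mechanics, then geometric
  compatibility (cortical nodes below the substrate are lifted to a 1 nm
  clearance every step; nuclear nodes outside the cortex are pulled back in
  along the local cortical normal every 10 steps — violations develop on
  much slower time scales than the step), then the Monte Carlo adhesion
  chemistry, fiber lifecycle updates, polarity refresh (every 300 s), and
  the leading-edge/protrusion refresh. Event probabilities stay ≪ 1 at
  $\Delta t \le 10^{-2}$ s, so operator splitting error is negligible.
* **Determinism.** All stochastic draws (binding, rupture, ventral
  attempts, polarity noise) come from R's RNG seeded by `sim_config$seed`;
  identical configurations give bit-identical trajectories.
* **Degenerate inputs.** Zero-area triangles and coincident fiber endpoints
  raise errors naming the offending element; grazing projection rays
  (|n·ẑ| < 0.2) fall back to vertical rays; ties in nearest-node searches
  break to the lowest node id; fibers orthogonal to the polarity at birth
  classify as leading.

## What the simulations do and do not show

The test suite and the acceptance script run scaled-down versions of the
headline experiments: 30-minute migration runs for the low-vs-peak ligand
density ordering (the full biphasic sweep is 5 densities × 3 h × 5
replicates), two pooled 1-h runs for the leading/trailing fiber-lifetime
statistics, and 20-minute spreading runs per micropattern for the traction
ordering. These sizes keep a complete run on one CPU in minutes; they carry
more Monte Carlo noise than the full-scale experiments, which is why the
stochastic checks pool replicates and use ordering or wide interval
assertions rather than point equality.

The synthetic substrate is an idealized uniform (or sharply masked) ligand
field on a rigid plane: no substrate compliance, ligand diffusion,
degradation, or durotaxis; no catch-bond kinetics, adhesion-maturation
signaling, dorsal fibers or transverse arcs, cell–cell contact, or 3-D
matrix. Passing tests therefore validate the mechanochemical core — bond
kinetics, membrane elasticity, contractility, protrusion and their coupling
— not a quantitative prediction of any particular cell line's absolute
migration speed.

## Output formats

Per-frame aggregates (nucleus/cell centroid, contact area, traction stress,
bond and fiber counts) and the fiber event log are data frames with CSV
writers; meshes and ligand fields export as ASCII PLY and legacy VTK
POLYDATA with per-node or per-triangle scalars. A thin command-line wrapper
lives in `inst/scripts/simulate.R`.
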