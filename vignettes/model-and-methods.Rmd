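---
title: "Coupled discrete/continuum modelling of drug transport in the lung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled discrete/continuum modelling of drug transport in the lung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pulmosim` simulates how a blood-borne therapeutic agent, injected as a
bolus into the pulmonary artery, is advected through the lung's vascular
tree, crosses the capillary walls of individual alveoli into the
interstitium, and accumulates at (healthy or cancerous) tissue.  The
package couples two models that operate at different scales:

* a **vascular graph model (VGM)** for the non-capillary vessels
  (arteries, arterioles, venules, veins), which treats the vasculature as
  a network of Poiseuille resistors and advects the dissolved drug with
  the blood; and
* a **double-continuum model (DCM)** of a single alveolus, in which the
  capillary bed and the surrounding tissue are two superimposed porous
  continua exchanging fluid and solute through Starling and
  Stavermann–Kedem–Katchalsky transfer functions.

The two are joined at *upscaled nodes*: graph vertices that stand in for
an entire alveolar capillary bed.  Each upscaled node is internally
simulated by the DCM, and the fluid and drug it extracts from the blood is
fed back to the graph as sink terms.

# The vascular graph model

## Flow

Each vessel segment $ij$ carries a Hagen–Poiseuille resistance
$R_{ij} = 8 \mu_{ij} l_{ij} / (\pi r_{ij}^4)$.  The apparent viscosity
$\mu_{ij}$ depends on the vessel diameter and the tube hematocrit: the
hematocrit is interpolated from a monotone diameter lookup (strong
Fåhræus reduction below roughly 20 µm; the systemic value 0.45 in large
vessels), and the relative viscosity follows the Pries-type in-vivo
hematocrit/diameter relation, whose 45 %-hematocrit curve has the
characteristic Fåhræus–Lindqvist minimum near 7–8 µm.  We use the form
without the endothelial-surface-layer wall factor so that the cell-free
limit returns the plasma viscosity exactly; with the shipped hematocrit
table (H ≈ 0.18 at 8 µm) and plasma viscosity $10^{-3}$ Pa·s the relation
reproduces the constant capillary viscosity 0.0021 Pa·s used in the DCM,
which is the criterion by which the shipped defaults were fixed.

Mass balance at every interior node, with the optional gravity head
$\rho g \Delta z_{ij}$ and the upscaled-node sink $q_i$, gives a sparse
linear system for the nodal pressures,
$\sum_j (p_i - p_j + \rho g \Delta z_{ij})/R_{ij} + q_i/\rho = 0$,
solved by a sparse direct factorization.  The balance is implemented
volumetrically (flows in m³/s); mass and molar flows are recovered by
multiplying with the mass or molar density, which is equivalent for an
incompressible fluid.  Pressure-dependent vessel cross-sections
(compliance) are available through a fixed-point iteration
(area → resistance → pressure; relative tolerance $10^{-8}$, at most 50
sweeps) but are disabled in the example scenario, as is gravity.

## Drug transport

The drug mole fraction $x_i$ lives on the nodes, each of which owns half
the volume of its incident edges.  Advection uses the first-order upwind
flux (the upstream node's mole fraction travels with the signed edge
flow), degradation is first order with $k = \ln 2 / t_{1/2}$, and the
upscaled-node sinks remove drug at the rates the DCMs report.  Time
integration is explicit Euler under the CFL restriction
$\Delta t \le C \min_i V_i / Q_i^{\text{out}}$ ($C = 0.9$ by default).
Boundary nodes pass their net inflow out of the domain, so the scheme is
exactly conservative; the removed moles are booked as effluent.  A
coupling sink can transiently overdraw a nearly empty node, in which case
the value is floored at zero and the clipped moles are logged rather than
silently lost.  The bolus is a Dirichlet mole fraction (default
$10^{-6}$) held at the arterial root for a configurable duration
(continuous infusion by default).

## Network generation

The example network is generated from Strahler-ordered morphometry tables
of the human pulmonary arterial and venous trees (diameters from 13 µm at
order 1 to 30 mm at order 17).  Leaves are order 1; two equal orders
meeting increment the order, unequal orders keep the larger one.  A
strictly halving dichotomy can only produce power-of-two leaf counts, so
the generator admits Strahler-consistent continuations — an order-2
vessel may spawn an order-1 side branch and continue as order 2 — which
makes any leaf count $\ge 2^{n-1}$ reachable while keeping the labels
consistent under relabeling (the suite re-runs the labeling from scratch
and compares).  The default scenario couples an order-4→1 arterial tree
with 21 pre-capillary terminals to the mirror venous tree through 21
upscaled nodes, three of which carry tumor properties.  The exact
branching topology behind the published 21-terminal example is not
specified anywhere; only the counts and morphometry are reproduced, and
the layout is planar because the tables carry no spatial information.

# The alveolus model (DCM)

## Geometry and mesh

A healthy upscaled node is a spherical shell (inner diameter 140 µm, the
alveolar air space; outer diameter 364 µm: a 12 µm capillary sheet plus a
100 µm tissue layer).  A tumorous node is a full sphere of the same outer
diameter — the carcinoma has filled the alveolus.  We discretize with a
structured spherical $(r, \theta, \varphi)$ cell-centered finite-volume
mesh whose polar axis is the x-axis: the arterial feed is the polar cone
around $-x$ and the venous drainage the cone around $+x$ (half-angle 25°
by default).  Cell volumes and face areas are analytic, so the discrete
volume telescopes to the exact domain volume at any resolution.  The
default resolution is $(n_r, n_\theta, n_\varphi) = (4, 8, 6)$ — 192
cells per alveolus — which keeps the coupled 21-alveolus run cheap while
refining either angular direction changes volume-mean steady pressures by
under 2 % (checked in the suite).  The published work used an
unstructured vertex-centered ("box") mesh instead; we kept the fully
upwinded, fully coupled, implicit character but chose the structured
spherical grid because the geometry is spherically symmetric and the
original meshes are not published.

## Continua and exchange

Both continua satisfy Darcy continuity and an advection–diffusion
equation for the drug mole fraction, scaled by their volume fractions
($\varepsilon_t + \varepsilon_c = 1$):

* **Tissue**: permeability $K_t$ (isotropic), viscosity of interstitial
  fluid, porosity $\phi$ and tortuosity $\tau$ with effective diffusivity
  $D_\text{eff} = \phi \tau D$; lymphatic drainage
  $q_{ly} = L_{p,ly} (S_{ly}/V) \max(p_t - p_{ly}, 0)$ (clamped — lymph
  only forms when interstitial pressure exceeds lymphatic pressure; a
  config switch restores the unclamped linear form) and the matching drug
  clearance $q_{ly} x_t$; in tumor cells the lymphatic terms vanish and a
  receptor-binding sink applies instead.
* **Capillary**: porosity and tortuosity one; permeability from the REV
  upscaling (below), with zero component normal to the shell for the
  planar healthy sheet, and the isotropic Poiseuille estimate
  $K = r^2/8$ (r = 10 µm) throughout the tumor sphere.  Because the
  rotated healthy tensor has no radial component, the healthy capillary
  continuum is confined to the innermost radial layer, whose thickness is
  pinned to the 12 µm capillary sheet; in the tumor every cell is
  vascularized.  The azimuthal orientation of the sheet's anisotropy on
  the sphere is arbitrary, so the solver uses the mean of the two
  in-plane REV components as the tangential permeability.

Fluid exchange follows Starling's law,
$J_v = L_p (S/V)\, [(p_c - p_t) - \sigma(\pi_c - \pi_t)]$, and solute
exchange the Stavermann–Kedem–Katchalsky equation,
$q_x = P (S/V) \varrho_{mol} (x_c - x_t) + (1-\sigma_f) J_v
\varrho_{mol} \bar{x}$ with $\bar{x} = (x_c + x_t)/2$ — the arithmetic
mean replaces the logarithmic mean, which is singular at $x_c = x_t$.
The transfer molar density is the arithmetic mean of the blood and
interstitial molar densities (293.75 mol/m³).  Transfer terms enter the
two continua with equal magnitude and opposite sign, so drug leaving the
blood equals drug entering tissue exactly, per step.

Receptor binding in tumor cells follows
$dC_{RL}/dt = k_{on} c C_R - k_{off} C_{RL}$ with
$c = x_t \varrho_{mol}$ and $C_R = C_{R0} - C_{RL}$.  At fixed $c$ the
implicit update is linear in $C_{RL}$, so the complex is eliminated
locally per cell (it is not a global unknown) and receptor conservation
$C_R + C_{RL} = C_{R0}$ holds to machine precision.

## Boundary conditions

Capillary continuum: Dirichlet pressure and mole fraction on the arterial
and venous cone cells, copied from the two graph nodes adjacent to the
upscaled node; no-flow elsewhere (blood cannot leave the alveolus any
other way).  Tissue continuum: Dirichlet pressure on the outer boundary
(−1064 Pa healthy, the pulmonary interstitial pressure; +133 Pa tumor,
the low end of measured tumor interstitial pressures), no-flow on the
inner (air-facing) boundary, advective outflow for the drug (inflow
carries zero concentration).  The initial capillary drug profile is
linear in x between the two feeding values; tissue starts drug-free; each
subsequent step restarts from the previous final state.

## Numerics

Fluxes use two-point (TPFA) transmissibilities with distance-weighted
harmonic averaging of the face-normal permeability or diffusivity;
advective fluxes are fully upwinded by the face flow sign (ties broken
toward the first cell).  Time integration is implicit Euler with all four
fields solved fully coupled.  The nonlinear residual is driven below a
relative tolerance of $10^{-8}$ by a Newton-type iteration with
frozen-coefficient linearization: upwind directions, the lymphatic clamp
state, the Starling rate inside the solvent-drag term and the local
receptor linearization are frozen at the current iterate, the resulting
linear system is solved sparsely and the true nonlinear residual is
re-evaluated.  Because the pressure subsystem is linear given the clamp
state, the iteration typically converges in two sweeps; an equilibrium
state is recognized in one.  On non-convergence the step is halved and
retried (at most 5 halvings).  One-step errors contract as
$O(\Delta t^2)$, the global scheme is first order, and each step closes
the tissue drug ledger (storage + bound = transfer − lymph − boundary
outflow) to the solver tolerance; the suite asserts all three.

# REV permeability upscaling

The capillary bed of one alveolus is represented explicitly as a planar
honeycomb lattice of ~1800 segments (8 µm diameter, 10 µm bond length) in
the mid-plane of a 364 × 364 × 112 µm cuboid.  The directional
permeability is measured exactly as one would in the laboratory: fixed
pressures on all vessel endpoints crossing the two faces normal to the
probed axis, no-flow at the other four faces, a network flow solve at the
capillary viscosity, and $K = Q \mu L / (A \Delta p)$.  Linearity makes
the result independent of the probing pressures (asserted to machine
precision), a single spanning tube reproduces $\pi r^4 / (8A)$ to
$10^{-12}$, and small hand-built series/parallel networks match
closed-form conductance oracles.  Because the bed is planar, no endpoint
reaches the z-faces and $K_{zz}$ is exactly zero; after rotating the
tensor onto the spherical shell (a rotation taking the cuboid z-axis onto
the local surface normal), the component normal to the shell vanishes.

A geometric note: a honeycomb with 10 µm bonds clipped to a 364 × 364 µm
square can hold at most about 1550 interior segments (three edges per
hexagon of area $2.598 a^2$), so the requested count of 1800 is not
reachable with these stated dimensions.  The generator therefore reports
the exact count in its metadata and documents a ±20 % tolerance on the
request; the default bed lands near 1570.  Segment count affects only the
magnitude of the in-plane permeability, for which no unambiguous printed
reference value exists; the shipped capillary permeability
(5.18 × 10⁻¹⁴ m², tangential) is the mean of the x- and y-permeabilities
the package itself computes for the default bed, keeping the DCM
parameterization self-consistent with the upscaling module.

# Coupling

Per time step: (1) solve graph pressure/flow with the previous step's
fluid sinks; (2) take a CFL-stable transport step with the previous
step's molar sinks; (3) advance every upscaled node's DCM over the same
interval with boundary conditions read from its graph neighbors;
(4) volume-integrate each node's transfer rates and store them as the
sinks for the next step.  This lagged (sequential) coupling keeps the
graph system linear; quartering the step changes compartment totals by
under 1 % (asserted).  Exchange rates are evaluated at the end-of-step
state — the quadrature consistent with implicit Euler — so the reported
sinks match the DCM's internal balance exactly, and the one-step lag is
reported openly as an `in_transit` ledger entry rather than hidden.
Each upscaled node also presents an effective hydraulic resistance to the
graph: the capillary continuum is solved alone under a unit pressure
difference between the cones and $R_\text{eff} = \Delta p / Q$ is split
over the node's two upscaled edges.  $R_\text{eff}$ is cached per node
kind for the duration of a run (the published scheme gives no indication
of dynamic recomputation, and with rigid vessels it is constant).  With
the default parameters the tumor bed ($K = 1.25\times10^{-11}$ m²,
whole-sphere) is orders of magnitude more conductive than the healthy
sheet, so tumorous upscaled nodes show the smaller pressure gradient
across their edges — one of the qualitative signatures the acceptance
suite checks on the full example.

A global drug audit closes the run: net moles supplied at the inlet =
change in graph storage + degradation + effluent + transfer to tissue,
and transfer = tissue storage + bound complex + lymphatic clearance +
tissue-boundary outflow.  Both ledgers close to well under 0.1 % (the
graph side to machine precision; the tissue side to the Newton
tolerance).

# Parameters

All parameters live in a YAML scenario file with SI unit suffixes on
every key (`inst/extdata/default_scenario.yaml`); `load_config()` rejects
missing or unknown keys.  Registry values with established printed
sources (densities, porosities, tortuosities, volume fractions, oncotic
pressures, reflection coefficients, boundary pressures, half-life) are
taken as-is.  Several entries have no usable printed value and were fixed
once, from the literature on macromolecule transport in normal and
neoplastic tissue (chiefly the Baxter–Jain tumor transport work), before
any acceptance run:

| key | value | rationale |
|---|---|---|
| capillary wall $L_p$ (healthy/tumor) | 2.7e-12 / 2.1e-11 m/(Pa·s) | classic normal vs tumor hydraulic conductivities |
| wall diffusive permeability $P$ | 5.7e-10 / 5.7e-9 m/s | IgG-scale macromolecule, tumor ~10× leakier |
| lymphatic wall conductivity | 2.6e-9 m/(Pa·s) | matches the commonly used lumped $L_{p,ly}S_{ly}/V$ with $S_{ly}/V = 3$ m⁻¹ |
| tissue permeability $K_t$ | 3.7e-17 / 2.2e-16 m² | interstitial hydraulic conductivity × interstitial viscosity |
| interstitial viscosity | 1.2e-3 Pa·s | plasma-like interstitial fluid |
| receptor set $C_{R0}, k_{on}, k_{off}$ | 1e-4 mol/m³, 100 m³/(mol·s), 1e-4 s⁻¹ | ~10⁵ receptors/cell at tissue cell density; antibody-fragment-scale affinity |
| inlet mole fraction | 1e-6 | dilute tracer; results scale linearly with it |

The run defaults — 21 alveoli with 3 tumorous, 1064/199.5 Pa boundary
pressures, 11 s of simulated time at Courant 0.9 — are the example
scenario's stated conditions.

# What the generators emulate, and what they do not

The synthetic network reproduces the morphometric diameters/lengths, the
Strahler topology rules and the example's counts, but is planar, strictly
bifurcating and only four orders deep; it has none of the spatial
heterogeneity, gravity stratification or compliance of a real pulmonary
tree (both features exist in the code but are off in the example).  The
honeycomb bed reproduces segment dimensions, connectivity degree 3 and
planarity, not the pentagonal closure meshes or the curvature of a real
alveolar sheet.  The DCM assumes rigid tissue (no respiratory motion), a
spatially uniform single-REV permeability per node kind, no necrosis, no
angiogenesis or tumor growth, no red-blood-cell phase in the capillary
continuum, and no pulsatility anywhere.  Passing tests therefore
demonstrate internal correctness (conservation, convergence, closed-form
agreement) and the qualitative physiology of the example, not predictive
accuracy for a real lung.

# Known limitations

* The Strahler generator's continuation placement is one deterministic
  choice among many topologies with the same counts.
* The frozen-coefficient Newton is quasi-second-order near the solution;
  severely stiff receptor kinetics (k_on c ≫ 1/Δt) would slow it, which
  the step-halving fallback absorbs.
* The healthy capillary sheet is one cell thick radially; its in-sheet
  resolution is the angular resolution of the mesh.
* Exchange with the graph is lagged by one step; the audit reports the
  in-transit amount explicitly.
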