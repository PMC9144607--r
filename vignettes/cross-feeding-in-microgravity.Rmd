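---
title: "Model and methods: a cross-feeding community in microgravity, an RWV, and 1 g"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Microbial communities accompany every crewed mission, and ground studies of
"space microbiology" overwhelmingly rely on rotating-wall vessels (RWVs) —
fluid-filled cylinders rotated about a horizontal axis — as an artificial
analog of microgravity. Bacteria almost certainly cannot sense gravity
directly; what an RWV does or does not reproduce is the *fluid environment*
of weightlessness: quiescence, the loss of sedimentation, and the loss of
solutal natural convection. For communities that exchange growth substrates
(cross-feeding), transport physics is growth physics, so the fidelity of an
RWV is ultimately a question about coupled fluid dynamics, mass transfer,
and metabolism at the scale of individual cells.

`rwvsim` is a desk-scale, agent-based simulator of the canonical engineered
cross-feeding pair: a methionine-auxotrophic *Escherichia coli* ΔmetB that
secretes acetate while consuming lactose, and a methionine-secreting
*Salmonella enterica* that grows on that acetate. Each is obligately
dependent on the other in lactose minimal medium. The package couples four
layers on one structured grid and steps them together in three gravity
regimes (`MICROGRAVITY`, `RWV`, `ONE_G`):

1. **Fluid**: incompressible creeping flow in the co-rotating body frame,
   with centrifugal and Coriolis frame accelerations and solutal Boussinesq
   buoyancy, one term per metabolite.
2. **Cells**: Lagrangian point particles (equivalent Stokes spheres) moved
   by the quasi-steady balance of Stokes drag, centrifugal, Coriolis, and
   gravity–buoyancy accelerations.
3. **Metabolites**: advection–diffusion of lactose, methionine, and acetate
   on the parcel grid, exchanged with each cell through a film
   mass-transfer law.
4. **Metabolism and growth**: zero-order cross-feeding conversion inside
   each cell and a mass-transfer-limited Monod growth law whose
   half-saturation constant is inversely proportional to the cell's film
   coefficient.

## Domain and discretization

The domain is a 300 × 100 × 300 µm box of 5 × 20 × 5 µm fluid parcels
(60 × 5 × 60) — the smallest box that can hold two cells at an inoculation
density of 1e5 cells/mL per species. The x and z axes are periodic. The y
axis is the radial direction: the outer wall (y = 0, also the floor in
1 g) is a zero-velocity no-slip inlet, the inner wall a zero-normal-gradient
freestream outlet with the modified pressure pinned to zero. Scalars see
zero-normal-gradient conditions at both radial walls; the advective flux
through the outlet is tracked in the conservation ledger. The zero-gradient
scalar walls were chosen (the original boundary prescription covers only
velocity) to minimize artificial metabolite loss from what is a small
window inside a much larger vessel.

The flow solver is a staggered-grid (MAC) finite-volume scheme:
first-order upwind advection, backward-Euler implicit viscosity, and a
Chorin projection whose Poisson equation is solved exactly by FFT in the
periodic axes and a tridiagonal solve along y. The discrete divergence
after every step is at round-off (the enforced tolerance is 1e-8 1/s). The
momentum equation is solved with the fluid volume fraction set to one: the
cell loading never exceeds a fraction of a percent of the domain volume, so
the ε-weighting of the momentum terms is numerically irrelevant, while ε
still enters where it matters — the Sherwood correlation that controls
each cell's film coefficient. The momentum advection term is skipped
whenever the advective CFL is below 1e-6 (at the Reynolds numbers of these
flows, Re ≈ 1e-6, it is below round-off influence); verification cases run
with it active.

Scalar transport uses conservative upwind fluxes and the same implicit
machinery for diffusion, which preserves the field mean exactly. Diffusion
uses the global constant diffusivity of the active preset; effective
diffusivity does not vary with local biomass or an extracellular matrix,
so biofilm-like and liquid-like regimes are compared by switching the
global constant, not by resolving the matrix.

The buoyancy term uses deviations from the ambient reference medium, and
the instantaneous domain-mean buoyancy mode is subtracted before forcing:
the domain is a periodic window inside a closed vessel, and a uniform
density offset (for example, from metabolites accumulating everywhere) is
held by the vessel's hydrostatic pressure rather than being free to
accelerate the window's fluid along the periodic axes. Without this, the
rotating gravity component along x would pump a spurious, linearly
growing bulk oscillation in RWV runs.

In the rotating frame, solid-body rotation is rest: every run starts from
zero body-frame velocity. The laboratory gravity vector rotates in the
body frame, `g_body(t) = g (−sin ωt, −cos ωt, 0)`, which is what a frame
matched to the vessel's rotation requires; a `fixed_gravity_in_body_frame`
switch freezes it for sensitivity checks. The centrifugal acceleration is
applied as a uniform body force along −y (the rotation arm, 1 cm at
10 RPM, spans only ±1.5% across the box), and a uniform force is absorbed
exactly by the modified pressure, so frame terms alone cannot spin up the
co-rotating fluid — a property the test suite asserts.

## Cell mechanics

Cells are equivalent Stokes spheres, radius `r = (3 V_cell / 4π)^(1/3)`.
The velocity relaxation time under Stokes drag is ~1e-7 s, far below any
usable step, so integration is overdamped: each step solves the 3 × 3
linear force balance (drag + Coriolis + centrifugal + gravity–buoyancy,
buoyancy entering through the specific-gravity factor 1 − ρ_f/ρ_s) for the
terminal velocity and advances positions. In 1 g this reproduces the
closed-form Stokes settling speed to better than 1%; in the RWV the
rotating gravity vector makes cells sediment at the 1-g speed in a
rotating direction, tracing ~0.05 µm circles — the physical origin of the
elevated particle Reynolds number (~5e-8) that feeds the mass-transfer
correlation.

Colonies can move as independent particles (`INDIVIDUAL`), as one rigid
unit with summed drag and summed body forces (`RIGID_COLONY` — the
aggregate is treated as N independent Stokes spheres, the simplest
contract consistent with the observation that the choice does not matter
for growth), or not at all (`STATIC`). Floor-attached biofilm scenarios
use `STATIC`: a wall-supported biofilm does not sediment, and without this
the 1-g comparison would confound convection with a slow collapse of the
colony onto the floor (contact mechanics is not modeled). Cells reaching a
radial wall are clamped with zero wall-normal velocity and counted, never
silently lost.

## Mass transfer, conversion, and growth

Each cell exchanges with the parcel that contains it (the parcel is ~1000
cell volumes, so no kernel spreading is warranted) through a film law,
`d(pool)/dt = A_C h_S (S_f − S_C)`, with the film coefficient from an
empirical Sherwood correlation for particles in fluid parcels:

```
Sh = (7 − 10 ε + 5 ε²)(1 + 0.17 Re_P^(1/5) Sc^(1/3))
     + (1.33 − 2.31 ε + 1.16 ε²) Re_P^(7/10) Sc^(1/3),   0 ≤ Re_P ≤ 100
h_S = Sh · D_M / (2 r)
```

At `Re_P = 0` and ε = 1 this is the classical quiescent-sphere value
`Sh = 2`, giving `h_S = 1.06e-3 m/s` at the intermediate diffusivity — and
the RWV sedimentation Reynolds number raises it to ~1.14e-3 m/s. The
correlation coefficients are used exactly as printed in the source
correlation for dense CFD-DEM flows (they differ slightly from the classic
Gunn constants); the grouping is fixed in `sherwood()` and verified
against a hand-written copy in the tests.

**Conversion.** Metabolism is zero-order per cell: `k·mass` cell
equivalents of the limiting substrate per second (k = µ_max), converted to
`Y` cell equivalents of product (Y_AM acetate per methionine for
*E. coli*, which additionally draws one lactose per methionine through its
own film; Y_MA methionine per acetate for *S. enterica*). Conversion can
never exceed what the film delivers: when `k·mass > A_C h_S S_f` the cell
runs supply-limited at `A_C h_S S_f` and its internal concentration sits
near zero.

**Growth.** The growth law is Monod in the transmembrane difference,
`µ = µ_max ΔS / (K_S + ΔS)` with `K_S = ρ_c d_c µ_max / (6 Y_XS h_S)`.
This `K_S` is exactly the value that makes the linearized Monod demand
equal the film delivery capacity, which has two consequences worth
stating. First, with the biomass density expressed in cell equivalents
(ρ_c = 1/V_cell), the demand-limited growth ceiling is
`µ/µ_max = m·Y_XS / (1 + m·Y_XS)` — geometry and h_S cancel — i.e. ~33%
of µ_max at Y_XS = 0.5, consistent with the 30–35% relative growth rates
this community shows in rich transport conditions. Second, in a
flux-balanced steady state both ΔS and K_S scale as 1/h_S, so a uniform
change in the film coefficient (e.g. RWV sedimentation) cancels out of µ;
transfer-coefficient changes matter transiently and through spatial
redistribution, not through the steady-state operating point.

**Stiffness and the quasi-steady closure.** The film relaxation time is
`V_cell / (A_C h_S)` ≈ 1.5e-4 s, four orders below the chemical step.
Integrating the film ODE explicitly at any affordable step would
misestimate the transmembrane difference by the ratio of the two
timescales, so the intracellular substrate state is advanced to its
quasi-steady balance each step: `ΔS = conversion / (A_C h_S)`, capped at
`S_f`. The film law itself remains available (and unit-tested at
artificially small h_S, where the exact two-compartment exponential is
observable) and is used verbatim for product release, including the
kickstart stock, which consequently enters the surroundings within one
chemical step of inoculation.

**No second growth draw.** Biomass accrual (`mass ← mass·e^{µdt}`, no
division, no decay) is bookkeeping on top of the conversion flux; it does
not debit the metabolite pool a second time. Debiting growth separately
(at µ/Y_XS, which by the K_S identity above equals the entire film
delivery in the linear regime) would cap each species' pass-through at
half its uptake and drive the community loop gain to Y_AM·Y_MA/4 ≈ 0.47:
the shared metabolite pool would then collapse within seconds, which is
incompatible with this community's sustained growth over minutes. With
conversion as the cell's full catabolic throughput the loop gain is
Y_AM·Y_MA = 1.86 and the community bootstraps from the kickstart to a
steady growth rate, as observed.

**Parcel-level guards.** Within a chemical step a crowded parcel may be
asked for more substrate than it holds; all draws in a parcel are then
scaled to at most 90% of its content, and the realized ΔS (hence µ) scales
with the realized conversion. This is the discrete form of local
competition for a shared parcel and converges away as dt → 0 (the
time-step convergence test bounds its effect at < 2% on growth rates).

## Parameters and provenance

Main-text values: µ_max = 1.82e-5 1/s (*E. coli*), 9.09e-6 1/s
(*S. enterica*); intermediate diffusivity 5e-6 cm²/s; 10 RPM; 1 cm
rotation arm; domain and parcel geometry as above. The remaining constants
are package defaults chosen once, with the following rationale, and every
one is an explicit configuration key:

| quantity | default | rationale |
|---|---|---|
| V_cell | 0.436 µm³ (r = 0.470 µm) | the unique volume consistent with both the quiescent transfer coefficient 1.06e-3 m/s at D = 5e-10 m²/s and "~430 cells per 500 µm³ parcel when randomly packed" at the random-packing fraction 0.375 |
| ρ_f, ρ_s | 1000, 1100 kg/m³ | water; typical wet bacterial density (specific-gravity factor 1/11) |
| ν | 1e-6 m²/s | water at room temperature |
| Y_XS | 0.5 | typical heterotrophic biomass yield; sets the 33% demand-limited ceiling |
| Y_AM, Y_MA | 1.86, 1.0 | their ratio equals the baseline 1.86:1 community composition and the stated coupling of the two species' growth |
| D (biofilm, liquid) | 1e-10, 1e-9 m²/s | ~0.2× aqueous (dense matrix) and aqueous small-molecule diffusivity |
| β (all metabolites) | 2.2e5 per ce/µm³ | calibrated once so the strongest-convection case reaches the prescribed maximum cell-scale Péclet ≈ 0.05 (below) |
| S_ref | ambient medium (lactose 1e-3, others 0) | the Boussinesq reference must be the force-free background state |
| kickstart | 1e-5 (two cells) … 1e-8 (2000 cells) | inversely scaled with inoculation density; 1e-2 for the "high" two-cell case |

**β calibration.** The solutal expansion coefficient couples cell-
equivalent concentrations to fluid density and is not derivable from first
principles here, because the concentration *scale* of the simulation
depends on the metabolic closure (film-gated conversion yields colony
excesses of ~1e-6 ce/µm³). What is prescribed is the dynamical regime: the
maximum simulation cell-level Péclet number `|u|·2r/D ≈ 0.05`. β was
therefore calibrated with one linear-response run of the 1-g floor-biofilm
case at biofilm diffusivity (u_max is linear in β to excellent accuracy:
a 260 → 2.2e5 extrapolation landed at Pe = 0.0497) and frozen. All
convection results should be read as "at the prescribed Péclet regime",
not as predictions from molecular properties.

## Scenario generators

All initial conditions are generated programmatically from (recipe,
parameters, seed), bit-reproducibly:

* `place_dense_sphere()` — random sequential addition at volume fraction
  0.35 (just below the ~0.38 jamming limit of random sequential insertion;
  0.375 is the fraction the 430-cells-per-parcel statement implies).
* `place_gaussian_sphere()` — isotropic Gaussian scatter, overlap-
  rejected; σ defaults to twice the dense-colony radius (a loose
  aggregate; the original does not print its σ).
* `place_random_uniform()` — overlap-rejected uniform suspension.
* `place_two_cells()` — separations from contact (1 µm) to the maximal
  separation under the periodic metric, |(L_x/2, L_y/2, L_z/2)| ≈ 218 µm.
* `place_separated_colonies()` — one single-species Gaussian colony per
  species at maximal separation.
* `place_floor_biofilm()` — a floor-tangent sphere or one-cell-thick disc.
* `kickstart()` — stocks each cell with its own product, which the film
  law releases; an obligate community started without it never grows.

The generator emulates the study conditions (placements, densities,
kickstarts, durations of 2–5 simulated minutes), not real inocula: there
is no cell division, no motility or Brownian motion, no adhesion or
contact mechanics, and diffusivity is globally constant. Passing tests
therefore demonstrate the transport–growth coupling under these idealized
conditions, and say nothing about, e.g., colony morphogenesis or long-term
population dynamics.

## Orchestration and outputs

One chemical step (default dt = 0.1 s, equal fluid step; both
configurable, with an exact-quiescence fast path when nothing can move the
fluid) applies, in fixed order: fluid sub-steps → particle motion → void
fraction → per-cell kinetics and parcel exchange → product film release →
scalar transport → growth. Fixed ordering is chosen for reproducibility;
runs are deterministic given (config, seed), and halving all steps changes
two-cell growth rates by < 2%.

A per-metabolite conservation ledger (production, consumption, outlet
flux) is audited against the total inventory; closed microgravity runs
hold to ~1e-13 relative. Runs record per-species mean and quartile mass
and growth-rate series at a configurable cadence; a mean rate is reported
as steady when it varies by < 1% over a trailing 30 s window. Outputs are
a CSV time series, legacy-VTK snapshots of all fields, a JSON summary
echoing the full configuration and seed, and a YAML config round-trip.

Relative growth rates are reported as a percentage of µ_max under two
normalizations (`SPECIES` and `COMBINED` = sum of the two µ_max), because
the source's printed percentages are not reproducible under either single
convention; both are exposed.

## Problem sizes used in the checks

The shipped tests and the acceptance script use the standard study
conditions at desk scale: two-cell probes (240–300 s), 500-cell floor
biofilms (240–300 s), 2000-cell random suspensions (180–300 s), and a
colony-size sweep at 100–1000 cells (150 s each). The growth-rate series
of these scenarios reach the steady-detection criterion within 100–150
simulated seconds.

## Known limitations

* The metabolic closure (film-gated zero-order conversion) keeps the
  global ledger exact but produces lower absolute metabolite
  concentrations than a closure whose production is unconditional; the
  convection–growth coupling is correspondingly weaker, and 1-g
  convection slightly *redistributes away* a colocalized colony's
  metabolites rather than boosting its growth.
* Steady-state growth is insensitive to uniform changes in h_S (the K_S
  identity); transfer-coefficient effects appear only transiently or
  through spatial structure.
* First-order upwind advection adds numerical diffusion ~u·Δx/2, about
  10% of the biofilm-regime diffusivity at the calibrated Péclet maximum.
* ε feeds the Sherwood correlation but not the momentum equation or the
  scalar storage term; inside dense colonies (ε ≈ 0.6–0.9) the stored
  inventory is therefore approximated by the full parcel volume.
* No division, decay, maintenance, motility, Brownian motion, adhesion,
  or spatially varying diffusivity.
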