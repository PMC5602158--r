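---
title: "Modelling chemokine transport and gradient formation in the lymph node"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemokine transport and gradient formation in the lymph node}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lnchemosim)
```

# Scope and model structure

`lnchemosim` computes the steady-state extracellular distribution of the
CCR7 ligands CCL19 and CCL21 in an idealized mouse popliteal lymph node,
together with the receptor states that those distributions imply. The
model couples four layers:

1. **Geometry.** A quarter node (symmetry planes `x = 0`, `y = 0`) of
   diameter 1 mm: a 10 um subcapsular sinus (SCS) under the capsule,
   spherical-cap B-cell follicles abutting the sinus floor with the
   follicle/T-zone border 188 um below it, a T-cell area filling the
   cortex, a medulla below `z = -250` um whose sinuses reach the capsule,
   and afferent/efferent vessel stubs on the polar axis. The mesh is a
   structured spherical-coordinate finite-volume grid: the sinus is
   exactly two conforming layers, the follicle border falls on a grid
   break, and the probe lines along which gradients are measured are
   radial grid lines.
2. **Lymph flow.** Creeping flow (`Re ~ 1e-2`) through a permeability
   field: the sinus slot and vessel lumina carry their Poiseuille
   equivalents (`h^2/12`, `a^2/8`), the cortical parenchyma a Darcy
   permeability of 0.01 um^2 and the medulla 0.5 um^2. Transvascular loss
   follows the Starling relation with fixed driving pressures, giving a
   constant volumetric sink per porous region (~13% of afferent inflow at
   baseline). A single SPD pressure solve yields mass-conservative face
   fluxes; because the operator is linear, the low-flow scenarios are an
   exact rescaling of the baseline field. Floor shear stress uses the
   plane-Poiseuille closure `tau = 6 mu U / h`.
3. **Chemokine transport.** Two mobile species (CCL19, free CCL21) obey
   steady advection-diffusion-reaction equations discretized with
   first-order upwind advection (positivity over formal order: the
   sinus-floor boundary layers are steep and a bounded scheme keeps every
   concentration nonnegative). All immobile species are slaved to the
   mobile fields by closed-form local equilibria (below). The nonlinear
   system is solved by Picard iteration with Aitken acceleration; linear
   systems are solved by sparse LU with factorization reuse (defect
   correction) across iterations. Convergence demands a maximum relative
   field change below 1e-8; the per-species mass ledgers then close to
   solver precision (~1e-9 relative).
4. **Analysis.** Profiles along the interfollicular (IFR) and
   follicle-border (BFTC) arrows are resampled at 4.5 um, low-pass
   filtered with a 5-point (±9 um) zero-phase moving average, and
   differentiated centrally; single-number slopes are least-squares fits
   (border: a 25 um window straddling the border; IFR: the extremal
   gradient within 20 um below the sinus floor). Across-cell differences
   use 9/18/36 um spacings on the filtered series.

# Reaction network and closed forms

Volumetric species (nM): CCL19 `C19`, free CCL21 `C21u`, matrix-bound
CCL21 `C21b`, free matrix sites `Mfree`, and the CCR7 states `R`, `R19`,
`Rdes`, `Rint`, `R21u`, `R21b`. Matrix binding is first order
(`k1 = 9.3e-5 /nM/s` on, `k2 = 1.2e-4 /s` off). CCR7 binds all three
ligands with `lambda_on = 1e-3 /nM/s`, `lambda_off = 5e-3 /s` (Kd 5 nM);
only the CCL19 complex desensitizes (3e-3 /s), internalizes (5e-4 /s,
destroying the ligand) and recycles (3.75e-4 /s). Two conservation laws
hold exactly: the receptor total and `Mfree + C21b + R21b = Mtot` (a
matrix site stays attributed to its CCL21 molecule while that molecule is
receptor-bound; the network is silent on this bookkeeping and this choice
makes both conservation sums exact). The desensitized complex retains its
ligand; degradation is assigned to the internalization step, so the net
CCL19 sink is `lambda_des * R19` at steady state.

At fixed mobile concentrations the immobile subsystem has a closed-form
steady state (`ccr7_occupancy_equilibrium()`, `local_equilibrium()`): the
receptor partition follows from one conservation sum, and `C21b` couples
to it through the site budget; the two-field fixed point is contractive
and solved by damped iteration per cell. These closed forms serve both as
the PDE solver's closure and as oracles in the test suite, where they are
checked against brute-force ODE integration.

ACKR4 on the capsule ceiling (SCS and medullary portions alike, 61
molecules/um^2 from 30,000 receptors per 25-um LEC) is a four-state
surface model: competitive binding (`eta_on = 0.5 /nM/s`,
`eta_off = 2.25 /s`), internalization (`eta_in = 1 /s`, ligand destroyed)
and slow resurfacing (`eta_up = 2e-3 /s`). Resurfacing limits the
saturated flux to `eta_up * Atot`; because the internalized pool
sequesters receptor, the half-maximal flux sits near 0.013 nM — far below
the 4.5 nM binding Kd — so the ceiling is an efficient scavenger at sinus
concentrations. The flux enters the discretization as a Robin condition
with the surface uptake in series with diffusion across the half cell, and
the surface saturation is evaluated at the reconstructed wall
concentration.

Chemokine loss to blood combines the Starling convective drag `J_v C` (no
solute reflection; plasma concentration taken as zero) and a vascular
permeability term `P_vasc (S/V) C` with `P_vasc = 5e-7 cm/s` and regional
vessel surface densities of 0.015-0.03 /um.

# Parameters: measured, derived and calibrated

Measured/literature values (fixed): all kinetic rates above, the per-cell
maxima (30,000 CCR7, 30,000 ACKR4, 1e6 matrix sites), vascular
permeability, node geometry (1 mm diameter, 10 um sinus, 188 um border
depth).

Calibrated defaults (chosen once against the reported baseline
concentration, gradient and shear magnitudes, then frozen; never revisited
after the acceptance suite was run):

* afferent flow 10 uL/h and lymph viscosity 1.5 mPa s — set so the
  sinus-floor shear spans >5 dyn/cm^2 near the afferent entry to
  <1 dyn/cm^2 at the medullary end;
* effective diffusivities `D_eff_19 = 35`, `D_eff_21 = 12` um^2/s —
  within the tissue-hindered range for ~10 kDa proteins, the smaller
  CCL21 value reflecting transient matrix interactions;
* per-cell secretion maxima 2.3 (CCL19) and 7.6 (CCL21) molecules/cell/s;
* the cell-census table (`inst/extdata/cell_census.tsv`): counts and
  placements are anatomically motivated (1e6 T cells at 90% in the
  T-zone, 5e5 B cells at 85% in follicles, 1.6e5 fibroblastic reticular
  cells at 75% T-zone / 6% medulla, ...); expression values are
  normalized effective levels, with the B-cell CCR7 level (0.2), the FRC
  matrix-site level (0.85) and the sinus-lining LEC matrix capacity
  (0.08, giving ~95 nM of sinus binding sites) calibrated. The census is
  an editable input, not a measurement.

The census-to-field conversion is exact bookkeeping: per region,
`sum_k N_k P_kj EV_k X_max / (N_A Vol_j)` in nM, with region volumes from
the mesh; cell types are treated as homogeneously distributed within each
region, so all fields are piecewise constant (regional heterogeneity below
the region scale is deliberately out of scope).

# Numerical choices

* **Flow reduction.** Inertia is dropped and the thin sinus is treated by
  its lubrication closure, which turns the flow problem into one scalar
  SPD solve. This loses developing-flow details near the afferent opening
  but preserves the quantities the transport stage consumes: conservative
  fluxes, percolation rates, and the shear range (which the closure
  reproduces exactly for channel flow).
* **Upwinding** keeps the operator an M-matrix: the discrete maximum
  principle and nonnegativity hold unconditionally, which matters more
  here than second-order accuracy because the follicle border and sinus
  floor are concentration discontinuities in the coefficients.
* **Degenerate inputs** are detected rather than smoothed over: a
  produced species with no sink has no steady state and raises an error;
  negative concentrations beyond rounding tolerance abort the solve.
* **Problem sizes.** The default configuration (resolution 6, ~5.5e4
  cells) is used by the acceptance script; the shipped tests run the same
  physics at resolutions 2.5-5 (4e3-3.3e4 cells). The ensemble analysis
  runs at reduced resolution by design; its qualitative outputs (signs,
  significance tiers) are asserted at that resolution.
* **Tie-breaks.** Probe lines are radial, so the border window sits
  symmetrically around the tagged border radius; the 5-point filter
  shrinks symmetrically at series ends, preserving constants exactly.

# Scenarios

Six presets: baseline; ceiling-ACKR4 knockout; upstream ("skin") ACKR4
loss, modelled as 5 nM CCL19/CCL21 in afferent lymph; the combination
("global"); 1% lymph flow; and 1% flow without ACKR4. Comparisons use
probe-profile overlays normalized by the profile maximum, with
"indistinguishable" declared below 1%. The monotone response to
intermediate afferent concentrations is checked at 0, 2.5 and 5 nM; the
intermediate level is a documented choice.

# Sensitivity analysis

Seven inputs (CCL19/CCL21 production, CCR7 per cell, ACKR4 per cell,
matrix sites, two diffusivities) are sampled log-uniformly over x0.2-x5 of
baseline by Latin hypercube (bounds are documented defaults; the sampling
scheme and bounds are configurable). Outputs are the four gradient slopes,
the two nodal totals and the two efferent concentrations. PRCC is
rank-based partial correlation with Student-t significance on
`n - 2 - p` degrees of freedom; the +/- tier notation marks
`p < 0.01 / 0.001 / 0.0001`. The flow field is frozen across the ensemble
since no flow parameter is varied.

# What the model does and does not capture

The synthetic geometry and piecewise-constant fields emulate the
anatomical layout and census-scale composition of a resting node, not any
imaged specimen: passing tests demonstrate internal consistency
(conservation, closures, scenario logic) and reproduction of reported
magnitudes, not agreement with individual animals. Known limitations:

* no cell migration or chemotaxis — chemokine fields do not feed back on
  the census;
* gradients are established quantities; transients are out of scope;
* the capsule does not deform and flow is steady (no valves, no
  pulsatility);
* one efferent-lymph behaviour deliberately left as-is: because the
  printed scavenger kinetics make the ceiling an efficient sink at sinus
  concentrations, raising diffusivity increases wall capture at least as
  fast as it increases the leak into the sinus, so efferent
  concentrations *fall* with diffusivity here; reported sensitivity
  analyses find the opposite association. A dedicated test block records
  this discrepancy rather than hiding it: the levers that could change
  the regime (afferent flow, scavenger kinetics and coverage, capsule
  area) are all pinned by measured values or by the shear-range
  calibration.
* receptor-level noise, oligomerization and proteolytic processing of
  CCL21 are not modelled.
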