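# lnchemosim

Steady-state simulation of CCL19/CCL21 chemokine transport and gradient
formation in an idealized mouse popliteal lymph node.

## The problem

CCR7 ligands guide leukocytes into and through lymph nodes: CCL21 —
abundant, matrix-binding — decorates the paracortex, while CCL19 —
diffusible, the only ligand that desensitizes and internalizes CCR7 — is
made by T-zone stromal cells. The extracellular distribution of both, and
hence every CCR7-guided migration decision, emerges from the interplay of
production, diffusion, lymph flow, extracellular-matrix binding,
CCR7-mediated consumption, scavenging by the atypical receptor ACKR4 on
the subcapsular-sinus (SCS) ceiling, and loss to blood vessels. None of
these gradients except matrix-bound CCL21 can be visualized in situ, which
is what makes a quantitative transport model useful.

`lnchemosim` builds a quarter-symmetric 3D node (capsule, 10 um sinus,
B-cell follicles, T-cell area, medulla, afferent/efferent vessels) on a
spherical finite-volume grid, solves Darcy lymph flow with Starling
transvascular exchange, then solves the steady reaction–advection–diffusion
system

```
0 = div(D_eff grad C) - div(u C) + q(x) - sinks(C, x),   C in {CCL19, CCL21u}
```

with all immobile species (matrix-bound CCL21 `C21b`, and the CCR7 states
free/bound/desensitized/internalized) slaved to the mobile fields through
closed-form local equilibria, and ACKR4 scavenging applied as a saturable
flux boundary condition on the capsule ceiling. Downstream analyses:
probe-line gradient profiles, across-cell concentration differences
(9/18/36 um cells), knockout and low-flow scenario presets, and Latin
hypercube + partial-rank-correlation (PRCC) sensitivity analysis over the
seven key biological parameters.

## Worked example

```r
library(lnchemosim)

run <- run_scenario("BASELINE_WT", default_config(resolution = 5))
print(run)
#> Scenario run: BASELINE_WT (ACKR4 on, C_in 19/21 = 0/0 nM, flow x1)
#>   max CCL19 0.654 nM, CCL21u 5.4 nM, CCL21b 292 nM
#>   IFR peak slopes (nM/um): CCL19 0.00125, CCL21u 0.0137, CCL21b 3.16
#>   BF-TC border slopes (nM/um): CCL19 0.00399, CCL21b 7.63
#>   efferent CCL19 0.073 nM, CCL21u 0.358 nM
```

Reading the numbers: matrix-bound CCL21 dominates (~292 nM peak in the
T-cell area, against ~5.4 nM free CCL21 and ~0.65 nM CCL19); its
interfollicular gradient at the sinus floor (~3.2 nM/um) is two orders of
magnitude steeper than those of the diffusible species; across the
follicle/T-zone border at 188 um depth the bound-CCL21 slope (~7.6 nM/um
over a 25 um window) dwarfs the CCL19 slope (~0.004 nM/um). Free CCR7 in
the T-zone core is a few percent of total — nearly all receptor is held by
matrix-bound ligand.

Scenario presets mirror the classic perturbations:

```r
wt <- run_scenario("BASELINE_WT", cfg)
ko <- run_scenario("LN_ACKR4_KO", cfg, mesh = wt$mesh, maps = wt$maps,
                   flow = wt$flow)
compare_runs(wt, ko)$indistinguishable   # TRUE: ceiling ACKR4 alone does
                                         # not reshape intranodal gradients
```

Sensitivity analysis:

```r
pva <- run_ensemble(pva_design(n_samples = 100, seed = 1),
                    default_config(resolution = 3))
print(pva)        # PRCC sign table over 7 inputs x 8 outputs
```

A thin CLI lives at `inst/cli/lnchemosim`
(`lnchemosim scenario --name BASELINE_WT --config cfg.yaml --out runs/wt`).

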