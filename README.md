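# samsim

Simulation of stem-cell homeostasis and patterning in the *Arabidopsis*
shoot apical meristem (SAM).

The SAM keeps a small stem cell domain (SCD) at the shoot tip for the
lifetime of the plant. Stem cells secrete the CLAVATA3 (CLV3) peptide,
which represses the transcription factor WUSCHEL (WUS) in the organizing
centre (OC) beneath them; WUS drives a mobile signal that confers stemness
on competent outer-layer cells, closing a negative feedback that fixes the
size and position of both domains. `samsim` models this circuitry as five
coupled reaction–diffusion equations on a static 2-D Voronoi tessellation
of a longitudinal meristem section, and ships the classical genetic
perturbations as runnable, machine-checked scenarios.

## The model in brief

Per cell, with `L` the unweighted graph Laplacian (zero-flux boundaries):

    d[WUS]/dt  = w_ko * rho*(a_c + xi_c) * [facX]/(K_f+[facX])
                 * ([WUS]^2/(1+kappa_w [WUS]^2) + b_w) * R(Ctot)
                 - d_w [WUS] + D_w L[WUS]
    d[facX]/dt = nu_f - (WUS production term) - d_f [facX] + D_f L[facX]
    d[Y]/dt    = r_y [WUS] - d_y [Y] + D_y L[Y]
    d[st]/dt   = I(c) * r_st * [Y]^n/(K_y^n+[Y]^n) - d_st [st] + D_st L[st]
    d[CLV3]/dt = s_endo * r_c [st] - d_c [CLV3] + D_c L[CLV3]

`R(C) = 1/(1 + (k_rep (1-c1_ko) C)^n_rep)` is a switch-like CLV3 response;
`a_c` is a tip-peaked anchoring field (positional bias) perturbed once per
run by a small frozen random value `xi_c`; `I(c)` restricts stemness to the
outer layers of the dome surface. WUS and facX form an activator–substrate
pair (WUS production consumes facX), which self-organises a confined WUS
maximum; the WUS-signal/stemness/CLV3 chain places the stem-cell cap above
it and pushes it below the surface. Time stepping is implicit–explicit:
Crank–Nicolson for diffusion on the cell graph, second-order
Adams–Bashforth for the reactions, constant step, nonnegativity floor.
Every simulation runs a two-stage protocol: equilibrate the wild type from
facX = 0.01 everywhere (30000 time units), then apply the scenario and
integrate on (15000 units).

See the methods vignette (`vignettes/meristem-model.Rmd`) for the full
account: parameter provenance and calibration, numerical choices, outcome
descriptors, and known limitations.

## Worked example

```r
library(samsim)

geometry <- build_dome_geometry(seed = 1)   # 122-cell, 9-layer dome
params   <- sam_params()                    # canonical constants
wt <- wildtype_stage1(geometry, params, seed = 1, equilibrium_tol = 1e-6)
label_domains(wt$trajectory$final, wt$trajectory$final, geometry = geometry)
#> domain_labeling: OC 23 cells in 1 component(s); SCD 42 cells in
#> 1 component(s); overlap 0 ; adjacent: TRUE
```

The wild type self-organises one 23-cell organizing centre directly
beneath one 42-cell stem cell domain; the domains touch but do not
overlap, WUS is excluded from the tip cell, and the SCD centroid lies
tip-ward of the OC centroid.

```r
ko <- run_scenario(scenario_catalogue()$clv3_knockout, geometry, params,
                   seed = 1, stage1_cache = wt, equilibrium_tol = 1e-6)
ko
#> sam_run: clv3_knockout | final OC 41 SCD 45 overlap 18 | expected
#> oc_expansion : PASS
```

Switching off endogenous CLV3 from the equilibrated wild type expands the
OC from 23 to 41 cells, expands the SCD to the whole competent region, and
shifts the OC centroid 1.3 cell spacings toward the tip — unrestricted WUS
expression, as in the conditional knockout.

Other catalogue entries behave analogously: `clv3_overexpression_strong`
(uniform exogenous CLV3 at 1.5) collapses stemness to ~0.01% and WUS to
~1% of wild type with no recovery; `clv3_overexpression_medium` (1.0)
collapses stemness to ~19% transiently before WUS re-ignites;
`clv3_promoter_wus` coalesces the two domains (71% overlap). A thin CLI
(`inst/scripts/samsim`) exposes `simulate`, `sweep`, `report` and
`fixtures` subcommands over the same functions.

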