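---
title: "A dynamic model of stem-cell homeostasis in the shoot apical meristem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic model of stem-cell homeostasis in the shoot apical meristem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samsim)
```

## The biological problem

The shoot apical meristem (SAM) of *Arabidopsis* maintains a small stem cell
domain (SCD) at its tip for the lifetime of the plant. The stem cells secrete
the peptide CLAVATA3 (CLV3), which represses the transcription factor
WUSCHEL (WUS) in the organizing centre (OC) beneath them; WUS in turn drives
a mobile signal that confers stem-cell identity on competent cells above.
This negative feedback keeps the two domains at a stable size and position,
tolerates substantial variation in CLV3 levels, and can regenerate both
domains after the niche is destroyed.

`samsim` implements this circuitry as a deterministic reaction–diffusion
system on a static two-dimensional cellular tessellation — an artificial
longitudinal section through the SAM — and packages the classical genetic
perturbations (clv3/clv1 loss of function, graded CLV3 overexpression, WUS
knockdown, WUS misexpression from the CLV3 promoter, virtual laser ablation,
and structural model variants) as runnable, machine-checked scenarios.
Growth and cell division are deliberately outside the scope: the model
addresses homeostasis on a fixed tissue, where gene regulation is faster
than the cell cycle.

## Model structure

Five dimensionless species are tracked per cell $c$: $[WUS]$, $[facX]$ (a
hypothetical diffusible substrate), $[Y]$ (the mobile WUS-derived signal),
$[st]$ (stemness, a continuous cell-state variable) and $[CLV3]$
(endogenous CLV3, the stem-cell reporter). Writing $L$ for the unweighted
graph Laplacian of the cell adjacency (shared Voronoi walls, zero-flux at
the rim) the equations are, per cell,

$$
\begin{aligned}
\frac{d[WUS]}{dt} &= w_{ko}\,\rho\,(a_c+\xi_c)\,
  \frac{[facX]}{K_f+[facX]}
  \left(\frac{[WUS]^2}{1+\kappa_w [WUS]^2}+b_w\right) R([CLV3]_{tot})
  - d_w [WUS] + D_w (L\,[WUS])_c \\
\frac{d[facX]}{dt} &= \nu_f - \text{(the WUS production term)}
  - d_f [facX] + D_f (L\,[facX])_c \\
\frac{d[Y]}{dt} &= r_y [WUS] - d_y [Y] + D_y (L\,[Y])_c \\
\frac{d[st]}{dt} &= I(c)\, r_{st}\,
  \frac{[Y]^{n}}{K_y^{n}+[Y]^{n}} - d_{st} [st] + D_{st} (L\,[st])_c \\
\frac{d[CLV3]}{dt} &= s_{endo}\, r_c [st] - d_c [CLV3] + D_c (L\,[CLV3])_c
\end{aligned}
$$

with the CLV3 response
$R(C) = 1/\bigl(1+(k_{rep}(1-c1_{ko})\,C)^{n_{rep}}\bigr)$ and
$[CLV3]_{tot} = [CLV3] + [CLV3_{ext}]$.

The WUS/facX pair is an activator–substrate system: WUS production consumes
facX one-for-one, so a WUS maximum depletes its own substrate and inhibits
WUS laterally through the freely diffusing facX pool. WUS and stemness are
locally acting factors with weak leakage diffusion only; facX, the
WUS-signal and CLV3 diffuse freely. Stemness production is gated by the
binary competence indicator $I(c)$, which marks the outer two cell layers of
the dome surface (the flat base of the section is the cut through the stem
and is never competent).

Three functional forms deserve comment, because they carry the scenario
behaviour:

* **Switch-like CLV3 action** ($n_{rep} = 32$, threshold
  $1/k_{rep} \approx 1.4$). CLV3 barely affects WUS below the threshold and
  shuts production off above it. This single nonlinearity produces (i) the
  exclusion of WUS from the high-CLV3 tip, (ii) robustness of the OC to
  severalfold changes in endogenous CLV3 — the stem-cell domain shrinks
  instead, because its own CLV3 output is under negative feedback — and
  (iii) the sharp difference between uniform exogenous CLV3 at 1.0
  (below threshold once endogenous CLV3 has decayed: WUS re-ignites) and at
  1.5 (above threshold on its own: permanent loss). A graded (low-Hill)
  response reproduces none of these; the calibration could not recover the
  published knockout/overexpression asymmetry without it.
* **Saturating facX activation** ($K_f$). Without saturation, facX
  accumulation after WUS repression fully compensates any uniform CLV3
  dose, and strong overexpression never collapses the niche. The
  Michaelis form caps that compensation while preserving
  substrate-depletion patterning at the (low) facX levels inside the OC.
* **Slow stemness decay** ($d_{st} = 0.002$). Stem-cell identity is a
  persistent cell state. Mechanistically this makes CLV3 linger after WUS
  repression begins, which lets the WUS spot actually die during a
  medium-dose overexpression transient before the system recovers — the
  collapse-then-recovery time course.

The activating variant of CLV3 action (WUS expressed from the CLV3
promoter) mirrors the bounded repressive factor upward,
$R \mapsto 2 - R \in [1, 2)$. A naive sign flip of the high-Hill term is
unbounded and drives WUS production through six orders of magnitude; the
bounded mirror keeps the perturbation in the same fold-range as repression.

## Geometry and the anchoring field

The tissue is built once and never changes (except by ablation): cell
centres on concentric semicircular layers over a half-disc at roughly unit
spacing, jittered (Gaussian, sd 0.08) so the tessellation is generic;
adjacency from shared Voronoi walls, computed exactly by a
bisector-interval test; the outermost layer and the flat base form the
boundary. The default dome has 9 layers and 122 cells, in the
80–150-cell range that lets the published domain proportions fit while a
full two-stage simulation stays in the seconds range. All counts are
configurable.

The anchoring field $a_c \in [0.05, 1]$ biases WUS/facX production toward
the tip: a Gaussian (width 3) in geodesic (graph) distance from the tip
cell on top of a 5% floor. Geodesic rather than Euclidean distance keeps
the base corners of the section — which are close to the tip as the crow
flies but far along the tissue — at low production competence. The field is
frozen positional information, not dynamics: its stated role is to position
the self-organizing WUS maximum, and a spatially constant value is a
first-class alternative (`build_anchoring(g, mode = "constant")`). Each
cell's anchoring is additionally perturbed once, at initialisation, by a
uniform random value in $\pm \xi$ ($\xi = 0.02$), sampled from the run
seed; this frozen heterogeneity breaks the symmetry the patterning needs
and keeps every run bitwise reproducible.

## Parameters and calibration

`sam_params()` reads the canonical table
`inst/extdata/default_parameters.tsv`, which documents every constant, the
term it enters and whether its default is one of the published dimensionless
values or a calibrated choice. The published table of constants could not be
transcribed symbol-by-symbol (the typesetting does not survive text
extraction), so the mapping of values onto named constants is itself a
modelling decision: degradation rates ($d_w = d_f = 0.004$ an order of
magnitude below $d_c = 0.05$ — the WUS system is deliberately slower than
the CLV3 system, which is what buffers WUS against fast CLV3 fluctuations),
the three free-diffusion rates (0.02), the saturation constants
($\kappa_w = 0.6$, $K_f = 0.5$) and the basal facX source
($\nu_f = 0.002$) take published values; the remaining constants were
calibrated by the hierarchical decomposition the original work describes:
first the WUS/facX pair alone (a single confined WUS maximum of the right
size), then the signal–stemness–CLV3 chain driven by a fixed OC (a
stem-cell cap of the right extent), and finally the feedback couplings
(tip exclusion, knockout expansion, the overexpression series). After
freezing, no constant is adjusted per scenario: every published experiment
is reproduced by the documented knob settings alone.

## Numerics

Diffusion on the cell graph is stiff relative to the kinetics, so the
integrator is implicit–explicit: Crank–Nicolson (trapezoidal) for the
diffusion terms — one symmetric linear solve per species per step, with the
operators factorised once per stage since geometry and step size are fixed
— and second-order Adams–Bashforth for the reactions, bootstrapped by one
explicit-Euler reaction substep. The state is floored at zero after each
step and floor events are counted; at the defaults they do not occur. The
default constant step $\Delta t = 0.5$ keeps a 30000-unit stage within
60000 steps while the scheme tracks a fourth-order Runge–Kutta reference at
100-fold smaller steps to a relative accuracy of about $3\times10^{-6}$
over 200 steps (the test suite requires $10^{-4}$).

Equilibrium ("all derivatives reasonably close to zero") is declared when
the maximum instantaneous derivative over all cells and species stays below
$10^{-6}$ for ten consecutive checks (every 50 time units). The tolerance
is a deliberate choice: the slowest mode of the patterned state — the WUS
maximum creeping along the nearly flat top of the anchoring landscape —
relaxes at a few $10^{-4}$ per time unit, so a $10^{-8}$ tolerance is not
reachable within the stage-1 budget of 30000 time units, while at
$10^{-6}$ the wild type equilibrates in 9000–20000 units across seeds and
the residual drift is below $10^{-3}$ concentration units over a further
1000 units.

Every run follows the two-stage protocol: stage 1 equilibrates the
wild-type parameterisation from the canonical initial condition (facX at
0.01 in every cell, all other species at zero; 30000 time units); stage 2
applies the scenario knobs — and, for ablation, the edited tissue — to the
stage-1 end state and integrates for another 15000 units. The second
duration is interpreted in time units, like the first, where the original
wording mixes units and steps. Structural variants (no facX feedback,
constant anchoring) define a different model rather than a perturbation and
therefore apply in both stages.

## Scenario catalogue and outcome checks

`scenario_catalogue()` returns one recipe per published experiment, each
carrying the exact knob settings ([CLV3$_{ext}$], endogenous scale,
receptor background, $w_{ko}$, sign of CLV3 action, feedback and anchoring
flags) and a machine-checkable expected-outcome descriptor (domain counts,
centroid shifts, overlap fractions, collapse/recovery bounds), so the
catalogue doubles as a regression suite. Domains are discretised relative
to the wild-type equilibrium: a cell is OC if $[WUS]$ reaches 31% of the
wild-type maximum, SCD if it is competent and $[st]$ reaches 21% of the
wild-type maximum (maximum, not mean, is the reference — the thresholds are
fractions of the peak). The exogenous CLV3 of the overexpression scenarios
is modelled as a held uniform concentration entering the repression input;
this is the closed form of a uniform production term under linear decay
and zero-flux diffusion, and it keeps the state variable equal to
endogenous CLV3, the reporter used to read out stem-cell identity. The
recovery descriptor for the medium dose uses configurable bounds with
defaults of 20% (collapse) and 60% (recovery) of the wild-type stemness
total; "SCD above OC" is operationalised as the SCD centroid lying closer
to the tip than the OC centroid, which is robust to geometry details. For
the ablation scenario, "expressing cells" are those above the same
domain thresholds applied to the stage-1 equilibrium itself, with
stem-cell identity read from endogenous CLV3.

## What the generator emulates — and what it does not

The synthetic tessellation reproduces the qualitative organisation of a
SAM section: a dome of near-isotropic cells, outer-layer competence, a
tip-biased production field. It does not emulate real meristem imaging
data: there is no growth, no cell division or displacement, no L1/L2
clonal layering beyond the competence mask, no cell-size gradient, and no
receptor biochemistry (CLV1/CLV2/CRN enter only through the scalar
background knob). Conclusions from the scenario suite are therefore
statements about the feedback circuitry on a fixed tissue, not about
morphodynamics.

## Known limitations

Honest limits of the calibrated model, measured at the defaults and
asserted as expected failures in the test suite:

* **Partial recovery from medium overexpression.** The transient collapse
  is deep (stemness falls to ~19% of wild type) and WUS genuinely
  re-ignites, but the recovered stemness plateaus near half the wild-type
  total rather than above 60%: with one unit of exogenous CLV3 held in
  every cell, the re-formed OC must sit about one cell layer deeper than
  wild type, and the signal reaching the competent layers is attenuated
  accordingly. Configurations that recover more strongly saturate the
  wild-type SCD to the whole competent region and thereby lose the
  knockout's SCD expansion; the knockout was prioritised.
* **No regeneration after full niche ablation.** Removing every WUS- and
  CLV3-expressing cell removes the high-anchoring tip; at the calibrated
  ignition threshold the remaining rim cannot re-ignite WUS.
* **The no-feedback variant overproliferates only partially.** All
  competent cells do acquire stemness, but WUS expression reaches ~25% of
  cells rather than a majority: the CLV3 switch still shuts WUS off
  beneath the saturated stem-cell layer.
* **OC size drifts in the endogenous-CLV3 sweep.** The stem-cell domain
  responds (43 to ~21 cells from 90% to 620%) while the OC count varies
  between ~24 and ~8 rather than staying exactly constant: the WUS maximum
  descends along the rising CLV3 contour into narrower, lower-anchoring
  layers. The discrete SCD counts also show single-cell non-monotone blips
  at the 10% sweep resolution.
* **Patterning is ignition-based, not a linear Turing instability.** With
  the saturating facX activation the homogeneous WUS/facX state is
  linearly stable on the cell graph; patterns arise from noise-seeded
  ignition plus substrate depletion, shaped by the anchoring field.
  Consequently, under spatially constant anchoring the calibrated model
  ignites the whole dome (at the default constant level) or nothing (at
  low levels) instead of forming a confined WUS maximum at a
  noise-selected location.

## A worked run

```{r example, eval = FALSE}
geometry <- build_dome_geometry(seed = 1)
params <- sam_params()
wt <- wildtype_stage1(geometry, params, seed = 1, equilibrium_tol = 1e-6)
lab <- label_domains(wt$trajectory$final, wt$trajectory$final,
                     geometry = geometry)
lab
#> domain_labeling: OC 23 cells in 1 component(s); SCD 42 cells in
#> 1 component(s); overlap 0 ; adjacent: TRUE

ko <- run_scenario(scenario_catalogue()$clv3_knockout, geometry, params,
                   seed = 1, stage1_cache = wt, equilibrium_tol = 1e-6)
ko
#> sam_run: clv3_knockout | final OC 41 SCD 45 overlap 18 | expected
#> oc_expansion : PASS
```
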