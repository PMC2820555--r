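Package: samsim
Title: Simulation of Stem-Cell Homeostasis in the Arabidopsis Shoot Apical Meristem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, scriptable simulator of stem-cell niche patterning in the
    Arabidopsis shoot apical meristem. Two coupled feedback systems -- a
    WUSCHEL/substrate activator-substrate pair and the WUS-signal/stemness/CLV3
    chain -- are integrated as reaction-diffusion dynamics on a static
    two-dimensional Voronoi tessellation of a longitudinal meristem section.
    Diffusion is treated implicitly (Crank-Nicolson) and reactions explicitly
    (Adams-Bashforth) on the cell graph with zero-flux boundaries. The package
    reproduces wild-type organizing-centre / stem-cell-domain patterning and a
    catalogue of in-silico perturbations: clv3 and clv1 loss of function, graded
    CLV3 overexpression, WUS knockdown, WUS misexpression from the CLV3 promoter,
    laser ablation, and structural model variants, together with threshold-based
    domain detection and outcome checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
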