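Package: angiophase
Title: Hybrid Phase-Field Simulation of Coupled Tumor Growth and Angiogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional hybrid continuum-discrete simulator of vascular
    tumor growth. Tumor tissue and capillaries are represented by phase fields
    (a tilted double-well Allen-Cahn equation for the tumor and a reactive
    Cahn-Hilliard equation for the vasculature), nutrient and tumor angiogenic
    factor (TAF) by reaction-diffusion equations, and tip endothelial cells by
    discrete chemotactic agents with Dll4-mediated lateral inhibition,
    filopodia-based capillary detection and anastomosis. The package ships
    scenario configurations for avascular growth, the angiogenic switch, and
    Dll4-blockade experiments, together with observables (tumor area, relative
    growth, capillary area, network-functionality statistic) and CSV/VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
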