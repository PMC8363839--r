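Package: membranekit
Title: Membrane Curvature, Thickness, Density and Lateral Diffusion
    Analysis for Lipid Bilayer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the biophysics of lipid bilayers from
    molecular-dynamics trajectories and atomic-force-microscopy topographs.
    Fits each leaflet's phosphorus-atom coordinates to a truncated
    two-dimensional Fourier series in the Monge gauge and derives
    mean-curvature and thickness fields; quantifies protein-induced
    curvature footprints; builds two-dimensional number-density maps of
    selected lipid species; estimates lateral diffusion constants from
    multi-origin mean-squared displacements via the Einstein relation;
    computes area per lipid and dose-effect trend reports; and measures
    supported-lipid-bilayer step heights from AFM images by cross-sectional
    line profiling. A synthetic-data module generates bilayer trajectories,
    Brownian ensembles, analytic test surfaces and AFM images with retained
    ground truth so every estimator is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    bio3d,
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
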