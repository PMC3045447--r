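Package: xpcilung
Title: Propagation-Based X-Ray Phase-Contrast Lung Micro-CT Simulation and
    Alveolar Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, verifiable pipeline for in-line (propagation-based)
    X-ray phase-contrast computed tomography of the air-filled lung. Generates
    parameterized digital mouse-lung phantoms (bifurcating airway tree,
    terminal alveoli of known diameter, ribs) with analytic ground truth;
    simulates phase-contrast projection formation by Fresnel diffraction of a
    complex-refractive-index object (exact angular-spectrum and linearized
    weak-object propagators); reconstructs slices by parallel-beam filtered
    back projection; segments ribs, whole airways and the bronchial tree by
    histogram-valley thresholding and seeded 3D region growing; and quantifies
    individual alveoli (equivalent and Feret diameters, diameter ratio,
    surface area from iso-surface meshes). Includes TIFF/CSV/STL/PLY/OBJ
    readers and writers and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
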