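Package: poremorph
Title: Morphometry, Symmetry Analysis and Model Building for Pore-Forming
    Oligomers in AFM Topographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify membrane-inserted pore-forming protein
    oligomers (gasdermin-type rings, arcs and slits) in atomic force
    microscopy (AFM) height maps. Includes a synthetic topograph generator
    with tip-convolution and scan-drift models, preprocessing
    (trace/retrace averaging, plane leveling to a membrane baseline,
    slow-axis drift unwarping, pixel-size calibration), particle
    morphometry (maximum height, crest diameter, pre-pore/pore
    classification), stoichiometry determination by rotational power
    spectra, iterative correlation averaging with rejection and n-fold
    symmetrization, geometric construction of ring/arc/slit/linear
    oligomer coordinate models from a monomer, and per-subunit structural
    metrics (head-domain orientation angles, inter-subunit hydrogen-bond
    and salt-bridge counts, C-alpha RMSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
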