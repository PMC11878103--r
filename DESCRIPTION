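Package: ccsim
Title: Cardiac Conduction System Phantoms and Monodomain Activation Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates labeled voxel phantoms of the human heart including the
    cardiac conduction system (sinus node with discrete exit pathways,
    atrioventricular node, His-Purkinje network with ventricular insertion
    points), simulates electrical activation with an isotropic monodomain
    reaction-diffusion model using a minimal six-current ionic model, with
    label-pair coupling rules that encode sinus-node exit pathways,
    atrioventricular insulation and Purkinje insertions, and measures
    label-volume morphometrics (wall thickness, chamber diameters, structure
    volumes). Includes label-volume input/output (multi-page TIFF and raw
    with JSON sidecar), majority-vote label downsampling, binary STL surface
    export, conduction-velocity calibration, and sinus/ectopic activation
    protocols with per-region activation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    tiff,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
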