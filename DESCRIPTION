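Package: hemowall
Title: Pulsatile Hemodynamics and Wall Shear Stress Index Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the hemodynamic environment of large arteries
    from pulsatile flow physics and wall shear stress (WSS) fields: a Carreau
    shear-thinning blood rheology model, an implicit axisymmetric solver for
    pulsatile flow in a rigid tube with analytic Womersley and Poiseuille
    oracles, endothelial wall indices (time-averaged WSS, oscillatory shear
    index, relative residence time, endothelial cell activation potential)
    computed per cell on triangulated surface meshes with threshold-area
    mapping, aortic pressure-waveform morphology (systolic peak, dicrotic
    notch, end-diastolic pressure) and waveform comparison metrics, a mesh
    independence (grid convergence) procedure with consecutive-mesh percentage
    differences and coarsest-acceptable-mesh selection, and a deterministic
    synthetic-data generator producing waveforms, tube surface meshes and WSS
    vector series with machine-readable planted ground truth.
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
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
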