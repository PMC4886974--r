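Package: protonCT
Title: Proton Computed Tomography Simulation and List-Mode Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale proton computed-tomography (pCT) toolkit: Bethe-Bloch
    stopping-power physics with CSDA range and water-equivalent path length
    (WEPL) conversion, a condensed-history Monte-Carlo transport engine for
    protons traversing a four-plane silicon-strip tracker telescope and a
    cylindrical insert phantom (Highland multiple-Coulomb-scattering model,
    optional Bohr energy straggling), detector-design sweeps over strip
    thickness and inter-tracker distance, straight-line-path sinogram binning
    of list-mode events, and three reconstruction back-ends (ramp-filtered
    back projection, SART, and total-variation-regularized iterative
    reconstruction) with contrast-to-noise-ratio and RSP-profile evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    optparse
Config/testthat/edition: 3
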