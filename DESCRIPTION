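Package: scatterbmd
Title: Scattered-Artifact Analysis for Bone Mineral Density Estimation in
    Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study Compton-scatter streak artifacts in cone-beam
    computed tomography (CBCT) as a carrier of bone mineral density (BMD)
    information. Provides a synthetic forearm-phantom slice simulator whose
    streak-artifact abundance follows a Compton scatter-intensity model
    (proportional to electron density, attenuated exponentially with depth),
    the artifact measurement chain (periosteal contouring by Hounsfield-unit
    thresholding, endosteal masking, interior subtraction, artifact-pixel
    counting over a 500-900 HU threshold sweep), and a linear
    count-to-density calibration with inverse prediction and a two-cohort
    low/normal BMD classifier. Image stacks are read and written as NIfTI
    volumes or 16-bit TIFF slice directories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
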