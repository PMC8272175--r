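Package: thyrotherm
Title: Bioheat Simulation of Dynamic Infrared Thermography of Thyroid Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of Pennes' bioheat transfer in a
    layered 2D neck cross-section containing a thyroid nodule, driven through
    a dynamic infrared thermography (DITI) examination protocol: steady state,
    forced fan cooling, and natural reheating. Includes a parametric neck
    geometry with tagged tissue regions, an unstructured triangular mesher,
    linear (P1) finite elements with convective, insulated and prescribed
    temperature boundaries, factorial sweeps over fat thickness, nodule size,
    metabolic heat and blood perfusion, skin-profile and probe-series
    extraction, thermogram time-series analysis (rebasing, consecutive
    differences, region-of-interest window means), and a synthetic thermogram
    generator emulating an infrared camera acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
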