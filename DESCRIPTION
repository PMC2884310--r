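Package: brachydose
Title: Point-Kernel Dose Engine for Intracavitary Brachytherapy Applicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic point-kernel dose-rate computation around encapsulated
    Cs-137 and Ir-192 brachytherapy sources inside heterogeneous applicators.
    Line sources are discretized into point emitters, source-to-detector rays are
    traced through a combinatorial solid geometry into per-material optical
    thicknesses, scatter is accounted for with geometric-progression buildup
    factors composed across material layers by the Kalos two-region rule, and
    energy fluence is converted to dose to water through mass energy-absorption
    coefficients. Includes builders for standard intracavitary applicators
    (tandem-and-ovoid LDR/HDR assemblies and a tungsten-shielded vaginal
    cylinder), Manchester reference-point plan evaluation, 3D dose grids,
    angular dose profiles and isodose contour extraction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
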