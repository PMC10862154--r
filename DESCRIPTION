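Package: canalmorph
Title: Intracortical Canal Histomorphometry from Bone Microradiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures intracortical remodelling in 2-D microradiographs of
    transverse cortical bone sections. Segments the cortex from periosteal and
    endosteal contours, binarises pore versus bone phases with the triangle
    (Zack) automatic threshold, detects individual canals by connected-component
    particle analysis with circularity and area filters, classifies canals by
    remodelling stage (cutting cone, closing cone, mature Haversian canal),
    computes section-level porosity indices (N.Ca, Tt.Ca.Ar, N.Ca/Ct.Ar,
    Tt.Ca.Ar/Ct.Ar), and compares groups with the Mann-Whitney U test. Includes
    closed-form basic multicellular unit kinetics and a seeded synthetic
    microradiograph generator with per-pore ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    igraph,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
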