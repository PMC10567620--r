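Package: tbpetsim
Title: Desk-Scale Sensitivity Simulation for Total-Body PET Scanner Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric geometry models, analytical 511 keV photon transport,
    and coincidence scoring for comparing the axial sensitivity of total-body
    PET scanner designs. Bundles a library of crystal-based (uEXPLORER-like,
    Biograph Vision-like) and axial plastic-strip (J-PET-like) tomograph
    configurations, samples annihilation events from a NEMA-style axial line
    source with an optional water phantom, applies oblique line-of-response
    suppression cuts (acceptance angle or ring difference), and computes
    per-slice sensitivity profiles, total-body sensitivity, photosensor
    covered area, and a cost-normalised figure of merit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
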