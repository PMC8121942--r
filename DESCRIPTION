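Package: ionpore
Title: Ion Permeation and Proteolipidic Pore Analysis for Membrane
    Protein Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ion conduction through proteolipidic
    pores of TMEM16 lipid scramblases in voltage-driven molecular
    dynamics simulations. Detects ion permeation events and blocked
    pore visits from per-protomer particle tracks, estimates mean and
    instantaneous single-channel conductances, classifies Na+/Cl-
    selectivity from permeation counts, computes lipid-headgroup
    density and orientation distributions along the pore axis, pore
    hydration profiles, neck-region inference and dilated-pore
    exclusion, headgroup-blockage geometry, contact probabilities,
    hydration-shell radii from radial distribution functions, and pore
    RMSD. Includes a computational-electrophysiology (CompEL)
    charge-imbalance controller and a synthetic trajectory generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
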