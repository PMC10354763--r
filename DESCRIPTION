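Package: droploop
Title: Closed-Loop Image-Feedback Control for Magnetic Digital Microfluidics
Version: 0.1.0
Authors@R:
    person("Platform", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A hardware-free simulation and control stack for magnetic
    digital microfluidics (MDM). Provides a deterministic physics-lite
    simulator of droplets and magnetic particle clusters on an open
    substrate (including magnet disengagement, particle extraction and
    surface-energy-trap anchoring), a synthetic annotated-frame renderer
    with COCO JSON interchange, a classical two-class object detector with
    IoU / per-class AP / COCO-style mAP evaluation, the four closed-loop
    droplet operations (transport, particle extraction, merging, passive
    mixing) as state machines with automatic failure rectification, and
    scripted in-vitro-diagnostic assay choreographies (BCA protein
    quantification and the Carba NP carbapenemase test) with colorimetric
    readout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
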