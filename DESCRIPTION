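Package: lipidgate
Title: Lipid Extraction and Salt-Bridge Analysis for Membrane Transporter
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of phospholipid extraction from the outer membrane
    leaflet by ABC-family transporters in coarse-grained or all-atom
    molecular dynamics trajectories. Implements leaflet assignment and a
    phosphorus reference plane, lipid lift histograms and membrane-mound
    detection, salt-bridge contact occupancy between charged residues and
    lipid choline/phosphate moieties, detection of the sequential
    salt-bridge ladder followed by a single extracted lipid, proximity
    -defined structural domains (gateway, annulus, annulus orifice), and a
    template-threading homology procedure with least-clash rotamer
    side-chain placement. Includes a seeded synthetic trajectory generator
    with planted ground truth so every analysis stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
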