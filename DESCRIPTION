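Package: epitissue
Title: Mechanical Simulation of Monolayered Epithelial Tissue Growth and Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A two-dimensional mechanical cell model for monolayered epithelial
    tissues. Cells are polygons with circular-arc free boundaries stored on a
    half-edge mesh; tissue dynamics are quasi-static, with per-step prescribed
    area changes relaxed to force balance under edge tension and intracellular
    pressure, and with all topological events (cell-cell contact, T1 edge flips,
    T2 void removal, birth, division, apoptosis) handled explicitly. Includes two
    application models: Delta/Notch-style bristle patterning with lateral
    inhibition, inhibition fields and expression stripes, and a stem/progenitor/
    differentiated lineage model of homeostatic tissue size control with Hill
    feedback. Tissues can be grown from a single cell, saved as text snapshots,
    and rendered to SVG.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
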