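Package: pulmosim
Title: Coupled Discrete/Continuum Simulation of Drug Transport in the
    Pulmonary Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the delivery of a blood-borne therapeutic agent
    through the pulmonary vasculature and into alveolar tissue.  A
    vascular graph model (VGM) solves Poiseuille flow and upwind drug
    advection on Strahler-ordered arterial and venous trees built from
    published morphometry; a double-continuum model (DCM) solves Darcy
    flow and drug transport in the alveolar capillary bed and the
    surrounding interstitium on a spherical-shell (healthy) or sphere
    (tumor) mesh, with Starling and Stavermann-Kedem-Katchalsky
    transvascular exchange, lymphatic drainage, first-order drug
    degradation and tumor receptor binding.  Capillary-bed permeability
    tensors are upscaled from discrete hexagonal capillary networks by
    representative-elementary-volume flow solves.  The two models are
    coupled through upscaled nodes whose fluid and drug exchange rates
    feed back into the graph as sink terms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
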