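Package: adsorbkin
Title: Physicochemical Characterization and Adsorption Kinetics of
    Globular Proteins on Macroion Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for characterizing a globular protein and
    its adsorption on macroion-coated surfaces: molecular geometry and packing
    limits from molar mass, nominal charge versus pH and isoelectric point,
    Stokes-Einstein hydrodynamic sizing, analysis of flow-cell (OWLS)
    adsorption traces by the transport-limited slope method with calibration,
    quartz crystal microbalance (QCM-D) Sauerbrey analysis with hydration
    correction, streaming-potential zeta potentials via the Smoluchowski
    relation, and a random sequential adsorption simulator of hard disks that
    reproduces the jamming coverage the packing limit relies on. Includes
    seeded synthetic-data generators for every trace type so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
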