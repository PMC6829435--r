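Package: gagposelab
Title: Post-Docking and Post-MD Analysis of Protein-Glycosaminoglycan Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for characterising how glycosaminoglycans (GAGs)
    such as heparin, chondroitin-6-sulfate and dermatan sulfate bind protein
    receptors, from the outputs of external docking and molecular-dynamics
    engines. Implements top-scored pose selection, DBSCAN clustering of docked
    poses under a periodic nearest-atom distance metric, binding-pose polarity
    classification relative to the reducing/non-reducing chain ends,
    per-residue binding-energy hotspot extraction and overlap matrices,
    fragment-based assembly of long GAG chains from docked trimer poses with
    RMSD deduplication, and calcium coordination-site detection with occupancy
    and replica-consensus reporting from trajectory frames. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable without external engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
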