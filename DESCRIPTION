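Package: ptmlandscape
Title: Temporal Landscapes of Post-Translational Modifications from Open
    Modification Searches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Postprocessing of open (unrestricted) modification-search
    peptide-spectrum matches into a temporal map of post-translational
    modification across a bacterial growth curve. Provides
    probability-ranked FDR filtering of PSM tables, mapping of peptide
    modification calls into protein coordinates, mass-shift spectra and
    amino-acid bias scores, exact-test enrichment of modifications at
    protein termini and between exponential and stationary growth phases
    with replicate-consistency filtering, fractional-modification
    trajectories and retention curves, sequence-window extraction for
    logo rendering, and a seeded synthetic PSM generator with planted
    modification regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stringi,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
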