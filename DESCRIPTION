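Package: ontoburst
Title: Sunburst Visualization of Ranked Drug and Disease Lists on the
    ATC and MeSH Ontologies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps ranked term lists (clinical trial counts, publication
    counts, frequencies) onto the Anatomical Therapeutic Chemical (ATC)
    drug classification, Medical Subject Headings (MeSH) disease tree
    numbers, or arbitrary ontologies parsed from OBO files. Provides
    bottom-up count propagation with a level cutoff, pruning of empty
    subtrees, threshold-based linear color scaling, and export of
    per-branch or tiled-summary sunburst plots as self-contained
    interactive HTML and as a portable JSON plot specification. Includes
    tab-separated and Excel template readers/writers, a MeSH descriptor
    XML parser, a seeded synthetic-ontology generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    optparse,
    readxl,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
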