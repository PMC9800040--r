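Package: sbgnyed
Title: Bidirectional Conversion Between SBGN-ML Process Description and yEd GraphML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless-where-possible translation of metabolic pathway diagrams
    between the Systems Biology Graphical Notation Markup Language (SBGN-ML,
    Process Description, milestone 2) and the GraphML dialect written by the
    yEd graph editor (yFiles extension namespaces). Implements the arc-port
    assignment algorithm for process glyphs (reversibility classification,
    Euclidean nearest-port assignment with farthest-arc repair, majority-side
    orientation inference), clone-marker detection, auxiliary-unit
    reconnection, a deterministic synthetic-map generator for testing at
    genome-scale map sizes, and a command-line interface with single-file and
    bulk conversion plus a structured conversion report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'pd-model.R'
    'yed-model.R'
    'report.R'
    'sbgn-io.R'
    'graphml-io.R'
    'sbgn2yed.R'
    'yed2sbgn.R'
    'equivalence.R'
    'fixtures.R'
    'cli.R'
    'sbgnyed-package.R'
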