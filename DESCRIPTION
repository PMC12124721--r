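Package: thiofluor
Title: Lipophilicity and Basicity Modeling of Fluorinated Thioalkyl Pyridines
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reduce shake-flask 19F NMR partition experiments to
    logD at pH 7.4, fit NMR pH-titration curves to obtain pKa values,
    assemble constitutional and DFT-derived molecular descriptor tables for
    2-(thiofluoroalkyl)- and 2-(sulfonylfluoroalkyl)pyridines, expand the
    tables with nonlinear transforms, scale them to the unit interval, and
    exhaustively search all one- and two-descriptor multilinear regressions
    against an experimental response such as logD or pKa. Ships the
    22-compound pyridine library with printed experimental values as a
    plain-text fixture, plus synthetic generators with known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
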