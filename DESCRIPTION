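Package: ireplan
Title: Statistical Treatment Planning for Irreversible Electroporation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning non-thermal irreversible electroporation
    (NTIRE) tissue ablation with a statistical, rather than deterministic,
    model of cell death.  Fits the Peleg-Fermi cell-survival law with
    pulse-number-dependent midpoint and width parameters to survival
    versus field-strength data, solves the dimensionless two-dimensional
    steady-state electric-field equation for two-electrode configurations
    by finite differences (validated against an exact image-charge
    solution), and composes the two into spatial cell-death probability
    maps with kill, transition and survive zone metrics.  Includes a
    synthetic survival-data generator, delimited-text and VTK exporters,
    and a command-line interface for the simulate/fit/plan workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
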