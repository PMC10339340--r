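Package: dcColoc
Title: Oligomeric State of Membrane Proteins by Dual-Color Colocalization SMLM
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Determines the oligomeric state of plasma-membrane proteins from
    dual-color single-molecule localization microscopy (SMLM/PALM) recordings
    using the dual-color colocalization (DCC) strategy. Provides readers and
    writers for per-channel localization tables (CSV, HDF5 and MATLAB
    dialects), DBSCAN-based clustering of localizations into fiducial beads
    and fluorescent-protein emission clusters, fiducial-based sample drift
    correction, linear lateral chromatic aberration correction, per-recording
    colocalization ratios within regions of interest, calibration of the
    indicator recall rate p and modification coefficient m on reference
    oligomers with bootstrap confidence intervals, coefficient-of-mismatch
    inference of unknown oligomeric states with a Kolmogorov-Smirnov
    alternative, and a generative simulator of dual-color SMLM recordings
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    rhdf5,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
SystemRequirements: Python (>= 3.8) with scipy on PATH, used only for the
    MATLAB (.mat) localization dialect.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
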