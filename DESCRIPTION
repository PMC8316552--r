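Package: autoquant
Title: Quantification of Autophagy and Lysosome Positioning Assays
Version: 0.1.0
Authors@R:
    person("Molecular Imaging", "Analysis Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the bespoke quantification procedures used in
    autophagy and lysosome-positioning studies: partition of single cells
    into concentric equal-area rings centered at the nucleus centroid and
    the per-ring normalized intensity-density profile, rolling-ball
    background subtraction, tandem mCherry-GFP-LC3 puncta detection and
    autophagic-flux scoring, rule-based transmission-electron-microscopy
    vacuole classification and morphometry, densitometry normalizations,
    and the associated group statistics.  A synthetic-scene generator with
    full ground truth makes every stage testable without real microscopy
    data.  Includes a command-line interface chaining simulation and
    analysis stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
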