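Package: dissim
Title: Dissolution Profile Similarity Testing for Pharmaceutical Equivalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control toolkit for in vitro dissolution testing of
    immediate-release solid dosage forms. Reads replicate or summary
    dissolution profiles (% label claim released over a sampling grid),
    converts chromatographic peak areas to cumulative % released with
    aliquot-withdrawal correction, screens replicate variability, and
    compares test products against a reference with the Moore-Flanner
    difference factor (f1) and similarity factor (f2) under the standard
    regulatory acceptance bands (f1 0-15, f2 50-100). Includes a seeded
    synthetic-study generator based on Weibull release kinetics so the
    whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
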