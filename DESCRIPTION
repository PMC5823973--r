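Package: mtflux
Title: Constraint-Based Modeling of Metabolic Rewiring Under Graded
    Mitochondrial Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to link graded mitochondrial respiratory-chain impairment to
    cytosolic redox rewiring with constraint-based metabolic modeling. Ships a
    central-carbon reconstruction (glycolysis, TCA cycle, malate-aspartate
    shuttle, respiratory chain, cytosolic reductive carboxylation) with carbon
    atom maps and hydride-transfer annotations; converts consumption-and-release
    (CORE) and complex-resolved respirometry measurements into flux constraints;
    solves flux balance analysis (FBA) and flux variability analysis (FVA)
    linear programs with a built-in two-phase simplex; performs reaction
    knockouts, ATP-contribution scans and between-condition flux differencing;
    predicts steady-state 13C mass-isotopologue distributions by elementary
    metabolite unit (EMU) decomposition and deuterium transfer through the
    cytosolic NAD(H) pool; and generates heteroplasmy-graded synthetic
    measurement panels with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
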