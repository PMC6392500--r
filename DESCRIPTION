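Package: nemaquant
Title: Quantification of C. elegans Mechanosensory Imaging and Behavioral Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mechanosensory neuron activity and
    behavioral endpoints in Caenorhabditis elegans. Implements ratiometric
    (YFP/CFP) calcium-imaging quantification with centroid region-of-interest
    tracking, decile background subtraction, bleed-through correction and
    responder classification; operational scoring of tap-evoked reversals,
    swimming-induced paralysis, thrash frequency and body-bend rate from
    posture and velocity traces; and population-level statistics (binomial
    confidence intervals, habituation curves, day-level quality control, and
    binomial logistic regression with single-step multiplicity-adjusted
    pairwise strain contrasts). Ships seeded synthetic-data generators for
    two-channel image stacks, tap-habituation event tables and swim traces
    so every stage can be validated against ground truth without external
    recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    yaml,
    jsonlite,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
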