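Package: ampliq
Title: Degenerate-Primer qPCR Quantification Bias Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: In-silico machinery for studying how target-gene sequence
    evenness and dominance affect absolute qPCR quantification with
    degenerate primer sets. Provides IUPAC-aware primer expansion and
    mismatch-tolerant binding-site search, log-normal artificial template
    mixture (gBTM) design with common- or rare-dominated abundance
    assignment, a theoretical binary amplifiability model, a synthetic
    amplification-curve generator with mismatch-dependent per-template
    efficiencies, Cy0-based absolute quantification (5-parameter Richards
    fits, tangent-at-inflection quantification cycle, standard-curve
    calibration), and theoretical-vs-empirical comparison statistics with
    Benjamini-Hochberg adjustment and a four-fold significance rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
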