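Package: slldscan
Title: Line-Specific Expression Outliers as Candidate Sources of Inbreeding
    Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects probe sets whose expression is extreme in sublines of a
    single inbred line and depression level (SL-LD outliers), the signature
    expected of line-specific genetic alterations causing inbreeding
    depression. Implements the Grubbs (extreme studentized deviate) statistic
    and its sequential per-probe outlier scan, SL-LD classification, a
    correlation-preserving randomization significance test that shuffles
    line/level codes across sublines, inbreeding-depression-rate and
    full-sib inbreeding-coefficient utilities, and downstream candidate
    characterization by pairwise correlation (with Benjamini-Hochberg
    correction) and complete-linkage clustering on absolute-correlation
    distance with bootstrap support. Includes a synthetic-data generator
    emulating a 4-line, 2-depression-level, 3-subline inbred microarray
    design so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
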