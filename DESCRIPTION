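Package: crisprec
Title: Analysis of CRISPR Spacer-Acquisition Recordings of Horizontal Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse CRISPR spacer-acquisition recording experiments
    that detect horizontal gene transfer (HGT). Amplicon reads of CRISPR
    arrays are parsed into spacers flanked by direct repeats, expanded
    arrays are identified, new spacers are classified endogenous versus
    exogenous with a two-step homology filter against the recorder strain,
    exogenous spacers are matched to reference databases at a stringency
    calibrated with a scrambled-spacer null, and transferred mobile elements
    are attributed by normalized spacer mapping, window coverage, PAM
    summaries and minimal covering plasmid sets. A synthetic recording
    generator with a ground-truth manifest makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
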