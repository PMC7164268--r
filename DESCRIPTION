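Package: seres
Title: Sequential Resampling Random Walks for Alignment Support Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric and semi-parametric resampling of biomolecular
    sequences by random walks that preserve neighboring residues, as an
    alternative to the site-i.i.d. standard bootstrap. Provides SERES
    (sequential resampling) walks over the columns of a fixed multiple
    sequence alignment and over unaligned sequences synchronized by
    high-similarity anchors, GUIDANCE-style residue-pair support estimation
    from re-aligned replicates, ROC/PR evaluation of support scores against
    a reference alignment, and a birth-death/GTR/indel sequence simulator
    for end-to-end testing. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
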