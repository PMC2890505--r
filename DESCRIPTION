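Package: methylarch
Title: Motif Architecture of Amino-Methyltransferases and
    Restriction-Modification Locus Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying DNA amino-methyltransferases
    (N6-adenine and N4-cytosine) into the alpha, beta and gamma motif-order
    groups, including detection of the DPPY-in-gamma-order subgroup with
    the auxiliary IVa and Xa motif blocks. Includes degenerate
    back-translation and inverse-PCR primer design from peptide sequence,
    a residue-set motif scanner with spacer support, endonuclease
    catalytic-site search, pairwise identity/similarity with
    conservation-group semantics, single (minimum) linkage unrooted
    distance trees, force-directed similarity layout, restriction-site and
    methylation-sensitive cleavage arithmetic, in-silico inverse PCR, a
    methylation-type evidence classifier, and seeded synthetic-data
    generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
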