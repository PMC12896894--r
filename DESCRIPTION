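Package: xylpscan
Title: Genome-Wide Identification and Characterization of Xylogen-Like Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterization of
    xylogen-like proteins (XYLPs), the chimeric arabinogalactan proteins that
    combine a PAST-rich glycomodule-bearing backbone with an eight-cysteine
    non-specific lipid-transfer protein (nsLTP) domain. Implements sequence-rule
    classification (PAST-rich region scanning, AG glycomodule detection, nsLTP
    cysteine-spacing motif matching), ProtParam-style physicochemical profiling
    (molecular weight, isoelectric point, GRAVY, instability and aliphatic
    indices, Kyte-Doolittle hydropathy profiles), neighbor-joining phylogeny
    with bootstrap support from Poisson-corrected protein distances,
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
    tandem/segmental/dispersed duplication classification by collinear
    chaining, promoter cis-element scanning against an IUPAC motif dictionary,
    expression-matrix clustering and 2^-ddCt relative quantification, and
    seeded synthetic-data generators that plant known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
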