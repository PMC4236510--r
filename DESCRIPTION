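Package: mipscan
Title: Sequence Analysis and Subfamily Classification of Fungal Major
    Intrinsic Proteins
Version: 0.1.0
Authors@R:
    person("mipscan", "maintainers", email = "mipscan@example.org",
           role = c("aut", "cre"))
Description: Annotated re-usable pipeline for characterizing Major Intrinsic
    Protein (MIP) channel sequences from fungi: validation of candidate MIPs
    (NPA boxes, six-transmembrane topology, interface conservation),
    extraction of the aromatic/arginine selectivity filter, NPA-motif
    substitution scoring, loop-D and loop-E features (length, charge, motif
    class, intra-helical salt bridge), physicochemical profiling (isoelectric
    point and molecular weight), distance-based phylogeny (neighbor-joining
    with bootstrap and majority-rule collapse) and combined rule/clade
    subfamily classification into AQP, aquaglyceroporin subgroups (Fps1-like,
    Yfl054-like, alpha, beta, gamma1, gamma2, delta), XIP and SIP-like.
    Includes a synthetic sequence generator with planted ground truth so every
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
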