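Package: karyofuse
Title: Detection of Chromosomal Fusion-with-Mixing from Macrosynteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for macrosynteny analysis of karyotype evolution:
    mutual-best-ortholog pairwise synteny tables (.psynt), Fisher exact
    tests of chromosome homology with Bonferroni correction, contig-level
    co-occurrence tests for fusion-with-mixing (FWM), a normalized
    sequence-turbulence statistic of chromosomal mixing built on exact
    distinct-subsequence counting, Oxford-grid dotplots with Ward-clustered
    axis ordering, and a karyotype-evolution simulator (fusion,
    fusion-with-mixing, fission, translocation, gene loss, draft-assembly
    fragmentation) that provides ground truth for every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'bigint.R'
    'AllClasses.R'
    'config.R'
    'io.R'
    'karyosim.R'
    'orthology.R'
    'homology.R'
    'mixing.R'
    'viz.R'
    'report.R'
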