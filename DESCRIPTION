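Package: ThripsCOI
Title: COI-Barcode Population Genetics of Onion Thrips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis of mitochondrial COI barcode populations of Thrips
    tabaci and related thrips: haplotype collapsing and naming, variable-site
    tables, pairwise nucleotide distances (p, JC69, K2P and a composite
    TN93-form estimator) with pairwise deletion, Neighbor-Joining phylogeny
    and clade-based lineage-group assignment, in-silico PCR typing of the
    reproductive mode (thelytokous 451-nt / arrhenotokous 261-nt fragments,
    heteroplasmy resolution via phylogenetic group), Nei within- and
    between-population diversity, chi-square homogeneity of reproductive
    modes across locations, Mantel tests of genetic versus great-circle
    geographic distance, distance-based species assignment across the COI
    barcode gap, and a seeded synthetic-population generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
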