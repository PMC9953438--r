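Package: polyrank
Title: Integrative Species Delimitation for Mixed-Ploidy Plant Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for rank decisions (species vs. subspecies)
    in polyploid plant groups, integrating four axes of evidence: SNP-based
    Nei (1972) genetic distances for mixed-ploidy VCF genotypes with principal
    coordinate analysis (Lingoes correction) and weighted ensemble k-means
    consensus clustering under fuzzy must-link/must-not-link constraints;
    elliptic Fourier leaf morphometrics and leaf dissection indices with
    permutation, NPMANOVA and Welch tests; SNiPloid-style per-SNP
    classification of parent-parent-child triplets for allopolyploid
    parentage scanning; environmental-PCA niche models with Schoener's D and
    Warren's I equivalency tests; and range approximation with permutation
    tests of sympatry. A rule engine (the 'Wettstein tesseract') turns the
    per-pair evidence matrix into explicit, auditable rank recommendations.
    Synthetic-data generators with known truth make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    xml2,
    vcfR,
    mgcv,
    cluster,
    pracma
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
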