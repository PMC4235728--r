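Package: arisacomp
Title: ARISA Fingerprint Processing and Comparison with Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes automated ribosomal intergenic spacer analysis (ARISA)
    electropherogram peak tables into fragment-length-bin OTU tables
    (fluorescence thresholding, regime-wise binning, intensity summation,
    relative-intensity filtering, technical-replicate quality control) and
    compares the resulting community fingerprints against 16S amplicon
    sequencing OTU tables: alpha diversity (observed OTUs, Shannon-Wiener H'),
    Bray-Curtis beta diversity, ANOSIM with exhaustive or sampled permutation
    p-values, principal coordinate analysis, Procrustes superimposition with
    Monte-Carlo significance, and Mantel-style correlation of similarity
    vectors. Includes a seeded generator of group-structured synthetic
    communities with paired pyrosequencing counts and ARISA peak tables, and a
    one-command comparison pipeline producing a reproducible report.
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
    vegan,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape,
    yaml
Config/testthat/edition: 3
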