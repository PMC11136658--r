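Package: tyrmotif
Title: Substrate-Specificity Analysis for the Tyrosine Kinome
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing tyrosine kinase substrate specificity from
    positional scanning peptide arrays: normalization of raw spot
    intensities into position-specific scoring matrices, sequence-logo
    height matrices, substrate scoring and percentile ranking against a
    reference phosphoproteome, promiscuity classification of
    phosphosites, inference of regulated kinases from differential
    phosphoproteomics by one-sided Fisher tests on favoured-kinase
    contingency tables, SH2-domain binding-motif processing and
    enrichment, Ward-linkage clustering of motif space with Newick
    export, and seeded synthetic-data generators with planted motif
    structure for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
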