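Package: coexcomp
Title: Differential Co-Expression and Comparative Genomics Screens for
    Teratogen Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary screens of species-variable
    teratogen response. The co-expression arm compares gene-gene Pearson
    correlations between control and exposed expression profiles,
    filters candidate pairs by correlation strength, tests the
    correlation difference with the Fisher z statistic under
    Benjamini-Hochberg false-discovery-rate control, classifies edges by
    sign change, and scores driver genes by binomial enrichment of their
    differential links; transcription-factor annotation against a
    TRRUST-style interaction table is included. The comparative arm
    screens ortholog protein alignments partitioned into phenotype
    groups for group-exclusive substitutions, maps them to reference
    protein coordinates, cross-references human variant tables, and
    compares gene neighborhoods and identity-thresholded paralog counts
    across species. A synthetic-data module generates expression
    matrices, alignments, and neighborhood tables with recorded ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
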