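Package: deacpredict
Title: Substrate-Selectivity Analysis for the HDAC6 Deacetylase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and predicting substrate selectivity of the
    histone deacetylase HDAC6 from acetylated hexamer peptides. Converts
    coupled acetate-assay time courses into initial velocities and
    Michaelis-Menten parameters (kcat, KM, kcat/KM) with detection-limit
    handling, calibrates reweighted-score cutoffs for a template-ensemble
    structure-based scorer consumed as Rosetta-style score tables, screens
    acetylome site tables against a FASTA proteome, builds position-specific
    scoring matrices for acetyl-lysine motifs, and harmonizes substrate calls
    across heterogeneous published-style datasets (SILAC ratios, array
    replica counts). Ships the benchmark peptide sets as plain-text fixtures
    and a seed-deterministic synthetic-data module so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rlang,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
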