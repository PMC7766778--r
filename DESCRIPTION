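Package: citmap
Title: Citrullination Site Mapping and Citrullination-Responsive Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps citrullination sites on fibrinogen chains from MALDI-TOF
    peptide-mass-fingerprint peak lists, using in-silico tryptic digestion in
    which citrulline blocks cleavage and phenylglyoxal monohydrate (PGM)
    derivatization adds a diagnostic +116 Da per citrulline, and classifies
    fibrinogen-regulated genes into citrullination-responsive modules with
    permutation-based gene-set enrichment scoring. Includes simulators for
    peak lists with planted citrullination sites and expression matrices with
    planted module structure, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
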