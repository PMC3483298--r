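Package: mspkit
Title: Design and Quantification Toolkit for Methylation-Specific PCR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico bisulfite conversion and primer evaluation for
    methylation-specific PCR (MSP) assays that discriminate unmethylated
    (beta-cell) from methylated (other-tissue) insulin-gene DNA, together
    with the full qMSP analysis calculus: standard-curve efficiency,
    delta-delta-Cq, Relative Expression Ratio and Demethylation Index
    quantification, replicate and inter-assay reproducibility statistics,
    and clone-level bisulfite methylation mapping with per-CpG exact tests.
    Includes seeded generators for synthetic fragments, dilution series,
    blood time courses and bisulfite clone reads so every analysis is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
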