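Package: coralRFLP
Title: In Silico PCR-RFLP Identification of Pocillopora damicornis Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the PCR-RFLP assay used to distinguish the cryptic
    Pocillopora damicornis lineages Type alpha and Type beta from other
    Pocillopora corals. Provides in-silico PCR (primer binding-site search and
    amplicon extraction, with a primer-specificity screen), virtual restriction
    digestion with AluI or user-defined enzymes, gel band-pattern prediction,
    classification of sequences or observed band sizes against a diagnostic
    pattern table, discovery of lineage-diagnostic indels in labelled
    alignments, enzyme ranking by diagnostic power, and a seeded generator of
    synthetic templates and sample panels that reproduce the assay's amplicon
    and fragment geometry. A command-line interface exposes the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
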