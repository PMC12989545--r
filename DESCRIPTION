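Package: strainmark
Title: Strain-Specific qPCR Biomarker Discovery and In Silico Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A genome-informed toolkit for discovering strain-specific qPCR
    biomarkers and validating them in silico. Screens a focal proteome for
    singleton proteins against a background panel by greedy identity/coverage
    clustering, refines candidates with Karlin-Altschul significance against a
    background database, designs real-time-PCR primer pairs under explicit
    GC/self-complementarity/amplicon-length criteria, predicts amplification
    products and mispriming on arbitrary genomes, classifies qPCR wells from
    Ct and melt-curve Tm, and scans a resequenced assembly for regions absent
    from a prior assembly. Ships deterministic synthetic-data generators with
    planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
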