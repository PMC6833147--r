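Package: gemkit
Title: Constraint-Based Analysis of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of compartmentalised
    genome-scale metabolic models (GEMs) of the kind used for yeasts such as
    Kluyveromyces marxianus: flux balance analysis with reduced costs and
    shadow prices on a built-in bounded-variable simplex, gene-protein-reaction
    (GPR) boolean logic, SBML Level 3 FBC v2 and tabular model input/output,
    biomass pseudo-reaction construction from macromolecular composition,
    minimal-addition gap filling against a universal reaction pool,
    transcriptomics-driven condition-specific model extraction with auxotrophy
    detection and rescue, biomass-precursor surplus-capacity analysis at fixed
    fractional growth, and sole carbon/nitrogen source phenotype screens.
    Includes a deterministic synthetic-data generator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
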