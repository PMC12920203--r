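Package: rhizorank
Title: Trait-Based Ranking and Consortium Design for Drought-Tolerant
    Rhizobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies in-vitro plant-growth-promoting trait (PGPT) assays
    of rhizosphere bacteria into indices and concentrations (solubilization
    halo indices, percent siderophore/phosphorus units, standard-curve
    colorimetry, gravimetric exopolysaccharides, PEG-6000 osmotic-stress
    growth), discretizes traits into five-level ratio scores, aggregates
    nutritional and drought-related categories into a strain ranking,
    assembles multi-strain consortia under pairwise compatibility
    constraints, and filters antimicrobial-resistance and virulence-factor
    hit tables by identity and coverage thresholds. Includes a synthetic
    assay-panel generator with planted ground truth for end-to-end testing,
    and bundled reference tables from a screening of 50 drought-tolerant
    grapevine rhizosphere isolates.
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
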