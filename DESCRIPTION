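Package: droughtscore
Title: Multi-Trait Drought-Resistance Scoring for Genotype Panels
Version: 0.1.0
Authors@R: person("Droughtscore", "Maintainers",
    email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comprehensive drought-resistance evaluation for genotype
    panels phenotyped under control and deficit irrigation. Implements
    fuzzy membership-function transformation of multi-trait data,
    principal component analysis on the correlation matrix with
    eigenvalue contribution rates, eigenvalue-weighted composite (F)
    and comprehensive (D) scores with genotype ranking, agglomerative
    clustering into resistance groups with SPSS-style rescaled
    dendrogram distances, Pearson correlation reports with significance
    stars, leaf-physiology assay calculators (malondialdehyde, relative
    water content, Arnon pigment concentrations, electrolyte leakage),
    and a seeded synthetic-panel generator with planted resistance
    structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    pheatmap
Config/testthat/edition: 3
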