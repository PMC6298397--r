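Package: epsflux
Title: Constraint-Based Analysis of Fungal Exopolysaccharide Metabolism
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building, curating and interrogating genome-scale
    stoichiometric models of exopolysaccharide (EPS)-producing fungi.
    Provides flux balance analysis (FBA) and its parsimonious variant on
    models read from tabular reaction lists or SBML Level 3 + FBC, medium
    definitions for growth-phenotype screening on sole carbon and nitrogen
    sources, single-gene-deletion essentiality for growth and for product
    synthesis, amino-acid supplementation scans, and a minimization-of-
    metabolic-adjustment (MOMA) overexpression screen that ranks reaction
    targets by the product of their biomass and EPS fold changes. A seeded
    toy-model generator emulating the nucleotide-sugar biosynthetic pathway
    ships planted ground truth so every pipeline stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
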