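Package: fbakit
Title: Constraint-Based Evaluation of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for evaluating stoichiometrically constrained
    genome-scale metabolic models of the kind distributed for budding
    yeast. Reads and writes SBML-encoded models (COBRA-style Level 2 and
    Level 3 'fbc' dialects), runs flux balance analysis, flux variability
    analysis and geometric FBA on a built-in bounded-variable simplex
    solver, simulates growth media, gene deletions and fractional flux
    restrictions through gene-protein-reaction logic, scores gene
    essentiality and auxotrophy predictions against curated gene lists,
    quantifies pairwise epistatic interactions under the multiplicative
    definition, and derives an evidence-only network reconstruction from
    a model by stripping reactions annotated with Systems Biology
    Ontology terms for encapsulating and omitted processes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
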