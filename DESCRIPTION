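Package: oncoflux
Title: Oncogene Inference from Genome-Scale Metabolic Networks by
    Trilevel Flux Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based screening of enzyme-encoding gene
    dysregulations that reprogram a normal-state metabolic network towards a
    cancer-state flux pattern. Reads paired SBML genome-scale models, parses
    gene-protein-reaction rules into a pseudo-enzyme table with isozyme
    detection, translates up/down/knockout dysregulations of chosen strength
    into mutated flux bounds, and simulates each mutant by flux balance
    analysis followed by a minimum-norm (uniform flux distribution)
    quadratic program. Mutants are scored against a cancer-versus-normal
    template of metabolite-flow (flux-sum) and flux log2 fold changes via
    similarity ratios and fuzzy-equal membership grades, combined into a
    single fitness; the outer search over genes, modes and strengths uses a
    nested hybrid differential evolution. Metabolite-flow variability
    analysis propagates flux-sum intervals through interval arithmetic to
    interval membership grades for robustness assessment, and a deterministic
    toy-network generator with planted dysregulations makes the whole
    pipeline testable without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    quadprog,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
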