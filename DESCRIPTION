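Package: fluxbal
Title: Flux-Balance Modeling from Curated Reaction Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing flux-balance models from database-style
    reaction tables and simulating them at steady state. Implements mass- and
    charge-balance checking, compound-class instantiation, the reaction filter
    cascade used when deriving a stoichiometric network from a curated database,
    two-stage flux balance analysis (objective maximization followed by taxicab-
    norm flux minimization), biomass objectives with growth-associated and
    non-growth-associated maintenance ATP, single-gene knockout essentiality
    screening scored against optical-density growth criteria, and phenotype-
    microarray style nutrient-utilization prediction with cross-dataset consensus
    scoring. Ships deterministic generators for small, fully balanced fixture
    networks (aerobic core energy metabolism and mixed-acid fermentation) and
    synthetic experimental datasets, so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
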