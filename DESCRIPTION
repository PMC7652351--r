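Package: evdesign
Title: Graph-Based Design of Epitope Vaccines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unified design of epitope-based vaccines (epitope mixtures,
    string-of-beads constructs, mosaic antigens, and polypeptide cocktails)
    as a team-orienteering problem on a weighted directed epitope graph.
    Builds epitope catalogs from antigen sequences, scores epitope-MHC
    binding, computes design-dependent edge weights (suffix-prefix overlap,
    proteasomal cleavage site likelihood), solves the resulting integer
    linear program with subtour elimination and coverage and conservation
    side constraints through the GLPK solver, traces the
    immunogenicity-cleavage Pareto frontier with the augmented
    epsilon-constraint method, and evaluates designs with population
    coverage, pathogen coverage, conservation, and positional entropy
    metrics. Includes a synthetic-data generator so the whole pipeline is
    testable without external predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: GLPK command-line solver (glpsol)
Config/testthat/edition: 3
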