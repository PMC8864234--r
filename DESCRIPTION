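Package: ethnoconsensus
Title: Quantitative Ethnobotany Indices, Consensus Analysis, and Co-Use Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of ethnobotanical surveys of
    medicinal plant use, modelled on surveys of the Kinmen islands. Computes
    the standard cultural-importance indices (use value UV, frequency of
    citation FC, relative frequency of citation RFC) and the factor of
    informant consensus (Fic) over ICPC ailment categories; implements the
    screen-by-Fic, inspect-Nur, rank-by-FC consensus interpretation; compares
    a survey against reference floras and materia medica catalogues (overlap,
    shared use, novelty detection, red-list tallies); mines informant-level
    species co-use association rules (support and confidence) and exports the
    derived network; and generates synthetic surveys with known ground truth
    so that every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
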