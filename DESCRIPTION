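Package: carofp
Title: Positional Chemical Fingerprints, Similarity and Chemotaxonomy for Carotenoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives positional chemical fingerprints for carotenoids from their
    IUPAC semi-systematic names, following the Nomenclature of Carotenoids.
    Provides weighted Tanimoto similarity search over fingerprints with
    inverse-occurrence category weights, rule-based structural classification
    (carbon number, end groups, fourteen structural categories) and prediction
    of six biological functions, plus organism carotenoid-profile comparison
    with lineage roll-ups and domain-of-life shared-set statistics. Includes a
    seeded synthetic name generator for round-trip testing and a small
    command-line interface.
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
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
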