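Package: epistasim
Title: Biology-Structured Simulation of Epistatic Case-Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates case-control genotype data from a hierarchical,
    biology-structured liability model in which six genetic variants (two
    transcription factors, an enhancer, a promoter, a coding variant and a
    microRNA variant) and an environmental factor are combined through a
    user-chosen chain of integer-valued mathematical functions. The exact
    liability distribution is computed by pushing the locus distributions
    through the function chain, disease status is assigned by a prevalence
    threshold, and samples are exported in the tab-delimited format used by
    the MDR software family. Includes entropy-based interaction-information
    metrics (main-effect, pairwise and pure three-way), a multifactor
    dimensionality reduction (MDR) classifier, standard and explicit
    (interaction-preserving) permutation tests, and heuristic search (random
    and genetic-algorithm) over the space of function combinations for models
    with strong three-way epistasis.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
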