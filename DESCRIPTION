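Package: eadiv
Title: Analytic Phylogenetic Diversity Under Sampling via the Edge-Length
    Abundance Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form sampling theory for phylogenetic diversity (PD).
    Summarizes a rooted metacommunity tree by its edge-length abundance
    distribution (EAD), the total branch length carried by edges with a given
    number of descendant tips, and from it computes the expected PD, the
    variance of PD, and the expected shared branch length and UniFrac distance
    of local communities assembled by binomial, Poisson, or negative-binomial
    (clustered or overdispersed) sampling. Replaces brute-force randomization
    nulls with analytic expectations, classifies observed communities as
    phylogenetically clustered, random, or overdispersed against a
    confidence band, normalizes UniFrac for unequal sample sizes, and ships a
    seeded Monte-Carlo oracle plus simulators for Yule trees and trees with
    exact power-law EADs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
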