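Package: lofscore
Title: Ranking Large-Effect Mutations by Evolutionary Information Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks nonsense mutations and frameshift indels in protein-coding
    DNA by the loss of alignment information content they cause (a position
    weight matrix based score D), scores indels in non-coding DNA by a
    phylogenetic log-likelihood-ratio (LLR) of the fitted evolutionary rate
    against the synonymous rate, and finds score thresholds separating
    strongly from weakly selected mutation classes by fitting Poisson
    random field models to site-frequency spectra. Includes the
    population-genetic validation machinery (allele-frequency spectra,
    exact and Kolmogorov-Smirnov tests, randomized mutation-placement
    nulls) and synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
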