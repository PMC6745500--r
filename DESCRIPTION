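Package: krabnet
Title: KRAB Zinc-Finger Protein Interactome Scoring and Evolutionary Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for affinity-purification mass
    spectrometry (AP-MS) interactomes of KRAB zinc-finger proteins (KZFPs).
    Scores bait-prey spectral counts against negative controls with a
    two-component Poisson empirical-Bayes mixture model (posterior
    probabilities and Bayesian FDR), applies the bait-expression,
    significance and subcellular-localization filter cascade, classifies
    baits by KAP1 recruitment strength (KAP1FC), and exports weighted
    interaction networks. Companion modules cover genomic-interval
    statistics (reciprocal overlap, Fisher exact enrichment, transposable
    element and TSS annotation), KRAB A-box evolution (p-distance
    neighbor-joining trees, standard/variant KRAB classification, consensus
    logos, Nei-Gojobori 1986 dN/dS with most-distant-ortholog averaging)
    and gene-level loss-of-function constraint Z-scores. Synthetic-data
    generators with serialized ground truth make every stage testable
    without access to deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    xml2,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
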