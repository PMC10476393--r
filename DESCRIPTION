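Package: keytaxa
Title: Key Gut Taxa from Abundance, Occurrence Frequency, and Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated workflow for identifying key bacteria in gut
    microbiome surveys by combining taxon abundance, occurrence frequency
    (persistent / intermittent / transient ecological categories),
    abundance-occupancy model fitting, random-forest feature importance, and
    weighted co-occurrence network modules correlated with clinical traits.
    Includes readers for taxon-by-sample feature tables with silva-style
    lineage strings, community-level statistics (Bray-Curtis, PERMANOVA,
    permutation Spearman, Welch and Kruskal-Wallis tests), a synthetic-data
    generator with planted ground truth for every stage, and an end-to-end
    pipeline producing a ranked key-taxa report with diagnostic-candidate
    flags.
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
    minpack.lm,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
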