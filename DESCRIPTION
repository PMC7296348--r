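Package: cortexfate
Title: Regional-Identity Analysis of Neural Directed-Differentiation Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of variation in neural directed-differentiation outcomes
    from targeted (nCounter-style) gene-expression panels. Implements control-probe
    normalization with outlier handling, expression filtering and log2 transform,
    cross-codeset merging via bridge samples, principal-component and
    Pearson-distance cluster analysis of regional variation, a marker-threshold
    classifier of regional differentiation outcomes with line-bias statistics
    (Newcombe/Wilson intervals), reference-atlas mapping scores from
    expression-energy profiles, the group-comparison statistics used alongside
    them, and a fully ground-truthed synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
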