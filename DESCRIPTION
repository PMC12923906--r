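Package: hippocampr
Title: Population Analysis of Hippocampal Calcium Imaging During Item-Place Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the post-extraction analysis of
    dorsal-CA1 wide-field calcium imaging recorded across an item-place
    learning design (habituation plus three object sessions). Provides
    behavioural scoring of object exploration and discrimination indices,
    cross-session ensemble recruitment and reactivation from a longitudinal
    cell-registration map, population-burst detection from z-scored calcium
    traces, place-cell-like classification from occupancy-normalised rate
    maps (Skaggs spatial information with a circular-shuffle null, field
    extraction, spatial coherence, object-vicinity scores), and functional
    connectivity networks built from pairwise Spearman correlations with
    weighted degree, clustering and closeness centralities. A synthetic-data
    generator plants ground-truth place fields, synchronous bursts,
    cross-session ensemble overlap and correlated cell blocks so that every
    stage is verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
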