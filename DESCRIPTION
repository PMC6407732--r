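Package: pairsearch
Title: Spatiotemporal Coordination Analysis of Paired Visual Search with
    Shared Gaze
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for collaborative and competitive paired
    visual search in which each searcher sees in real time which hexagonal
    grid cell their partner is looking at.  Provides the 5x5 hexagonal
    area-of-interest geometry, online gaze-marker (highlight)
    reconstruction with a majority-vote rule, dispersion-based fixation
    detection and dwell/transition event construction, dwell-overlap and
    scanpath-entropy coordination metrics, a simulated blind-pair
    baseline, nonparametric summary statistics (signed-rank PS_dep,
    Kruskal-Wallis eta squared, percentile bootstrap), and an agent-based
    paired-searcher simulator that generates ground-truthed gaze
    recordings for testing every stage without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
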