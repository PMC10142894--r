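Package: nodeffect
Title: Event-Locked Heart-Rate Variability Analysis of Nodding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how nodding relates to arousal via heart-rate
    variability. Reads time-stamped RR-interval recordings and behavioural
    annotations (including ELAN tab-delimited exports), computes sliding-window
    pNN50 and LF/HF series, derives a per-nod event-locked slope statistic with
    session-trend correction together with a matched non-nod baseline, and
    compares the three study conditions with a tie-corrected Kruskal-Wallis
    test followed by protected LSD pairwise comparisons. A synthetic-session
    generator with a known event-coupled autonomic effect provides ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
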