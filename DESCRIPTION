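Package: saltnet
Title: Two-State Weighted Gene Co-Expression Network Analysis for
    Stress Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from time-course
    RNA-seq count matrices sampled under a control and a stress condition,
    detects co-expression modules by topological-overlap clustering,
    correlates module eigengenes with time-point traits, and compares
    per-gene network centralities (degree, betweenness, closeness,
    clustering coefficient) between the two condition-specific networks to
    flag "key genes" that gain network importance under stress.  Includes
    median-of-ratios normalization, a negative-binomial Wald screen for
    differential expression, Fisher-exact term enrichment with
    Benjamini-Hochberg correction, and a synthetic-data generator with
    planted modules, stress-specific co-expression rewiring and a
    machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    MASS,
    mclust,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
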