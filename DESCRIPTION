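Package: physionetr
Title: Physiological Correlation Networks from Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted physiological networks from subjects-by-variables
    biomarker tables. Variables are linked when their Spearman rank correlation
    is significant under a Student-t test, edges are weighted by squared rho,
    and the resulting graphs are characterized by topology metrics
    (Krackhardt connectedness and efficiency, characteristic path length,
    Barrat weighted clustering, small-world indices, scale-free fit),
    centrality analysis (eigencentrality, Freeman flow betweenness,
    centralization, assortativity), community detection (Louvain, map
    equation) with partition-comparison metrics, conditional uniform graph
    and quadratic assignment permutation tests, two-network comparison, and
    targeted-attack robustness curves. A Gaussian-copula cohort simulator
    with planted correlation blocks provides fully reproducible test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
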