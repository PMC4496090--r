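Package: chainreg
Title: Chain-Graph Analysis of Lifestyle and Genetic Effects on Glycaemic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for graphical Markov (chain-graph) modelling of
    intervention cohorts via sequences of least-squares regressions.
    Provides SNP panel quality control (call rate, Hardy-Weinberg
    likelihood-ratio testing, linkage-disequilibrium checks), construction
    of unweighted genetic predisposition scores with mean-count imputation,
    derivation of HOMA insulin-sensitivity and secretion indices and
    log-ratio change outcomes, backward-elimination model selection with
    partial F-tests, prespecified interaction screening, assembly and DOT
    export of the directed/undirected association graph, path-based
    outcome predictions, and a synthetic-cohort generator with queryable
    ground truth for structure- and parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
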