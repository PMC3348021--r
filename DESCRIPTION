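Package: pdnsbic
Title: Pattern-Driven Neighborhood Search Biclustering of Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biclustering of gene-expression matrices by pattern-driven
    neighborhood search (PDNS), an iterated local search over a trinary
    behavior-matrix encoding of expression trajectories. Provides the
    behavior-matrix preprocessing, the Average Spearman's Rho (ASR) and
    Mean Squared Residue (MSR) coherence scores, pattern-based gene and
    column move operators, descent with perturbation restarts, greedy
    Cheng-Church-style and OPSM-style initializers, a synthetic-data
    generator with implanted trend-coherent biclusters, and recovery
    evaluation against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
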