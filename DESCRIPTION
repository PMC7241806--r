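Package: refstab
Title: Reference-Gene Stability Assessment for RT-qPCR with Mixed-Model ICC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for selecting stable reference (housekeeping) genes in
    RT-qPCR experiments. Implements the four classic stability algorithms
    (geNorm M with pairwise variation, NormFinder, BestKeeper, comparative
    delta-Cq), consensus ranking by weighted Spearman-footrule aggregation
    (exact assignment solution and cross-entropy Monte Carlo), and an
    intraclass-correlation stability measure for reference-gene combinations
    based on a three-way linear mixed-effects model with REML variance
    components, confidence intervals, likelihood-ratio tests for systematic
    treatment effects, combination search with a lower-bound stopping rule,
    and Bonett sample-size planning for ICC precision. Also provides
    replicate quality control, efficiency-corrected relative quantification,
    inter-plate factor correction, normalized relative quantities with error
    propagation, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
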