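Package: gutevolve
Title: Within-Host Evolution of a Gut Commensal: Simulation and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing experimental evolution of Escherichia coli
    colonizing the mouse gut in immune-competent and immune-compromised
    hosts. Provides a haplotype-class Wright-Fisher simulator of within-host
    clonal interference (beneficial sweeps, deleterious resistance alleles at
    mutation-selection balance, antagonistic pleiotropy across hosts, binomial
    plate sampling), together with the inference pipeline used on such data:
    fluorescent-marker divergence tests, selection-coefficient estimation from
    in vivo competition assays with variance and ANOVA comparisons, mutation-
    and transposition-frequency estimation at mutation-selection balance,
    division-rate inference by calibration-curve inversion of rRNA
    hybridization fluorescence, binomial sweep fits with cluster-robust
    errors, and clone-typing/haplotype statistics including parallel-target
    calling and host-specificity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
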