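Package: clonedrift
Title: Clonal Selection and Genetic Drift in Paired-Passage Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and quantifies clonal selection during in vitro cell
    aging from paired early/late-passage deep-sequencing allele counts.
    Models the experiment as a single 200-cell bottleneck followed by
    stochastic, fitness-proportional population growth (a modified Moran /
    Polya-urn division process), and provides a drift-null significance
    test with Bonferroni correction, maximum-likelihood estimation of the
    selection coefficient with a likelihood-ratio 95% confidence interval,
    a quality-aware somatic-variant screen on paired pileups, a
    sensitivity/specificity evaluator for doped DNA mixtures, and a
    synthetic-data generator that emulates the full experiment with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
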