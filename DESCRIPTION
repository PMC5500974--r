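Package: epiACO
Title: Ant Colony Optimization Search for Epistatic Interactions in
    Case-Control Genotype Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects epistatic (multi-SNP) interactions in case-control
    genotype data with an ant colony optimization search driven by the
    Svalue fitness, the ratio of the mutual information between a SNP
    combination and the phenotype to the logarithmic K2 Bayesian-network
    score.  Includes two adaptive path-selection strategies, a
    pheromone-update rule that rewards candidate solutions, and a memory
    of high-scoring combinations cut at the inflection point of the
    descending score curve.  Ships a two-locus penetrance-model simulator
    (Hardy-Weinberg backgrounds, exact conditional sampling of disease
    genotypes given case/control status), five benchmark disease models,
    an exhaustive-scan oracle, and a detection-power harness for
    simulation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
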