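Package: genoCaseControl
Title: Case-Control SNP Association with Inheritance Models and
    Allele-Frequency Perturbation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for single-SNP case-control association analysis from
    genotype count tables. Compares genotype distributions between
    populations with chi-square tests, fits unconditional logistic
    regression under the five classical inheritance models (codominant,
    dominant, recessive, overdominant, additive) with odds ratios, Wald
    confidence intervals, likelihood-ratio P values and AIC-based model
    selection, and quantifies the sensitivity of significance decisions to
    small minor-allele-frequency changes by perturbing a case dataset one
    genotype at a time. Includes a deterministic synthetic-data generator
    (Balding-Nichols population panels and retrospectively sampled
    case-control cohorts) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: SNP, GeneticVariability, StatisticalMethod, Genetics
RoxygenNote: 7.3.3
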