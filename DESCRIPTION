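Package: frailtymr
Title: Drug-Target Mendelian Randomization of Blood Pressure on Frailty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of genetically proxied
    antihypertensive drug-target modulation on deficit-accumulation frailty.
    Implements the deficit-accumulation frailty index with clinical category
    cutoffs, selection of drug-target genetic instruments from GWAS summary
    statistics (gene-region windows, significance and allele-frequency
    filters, greedy LD clumping), weighted and unweighted genetic risk
    scores with first-stage instrument diagnostics, one-sample Mendelian
    randomization by two-stage predictor substitution with a multinomial
    logistic second stage reported as relative risk ratios per clinically
    scaled blood-pressure decrements, and summary-data Mendelian
    randomization (SMR) with the HEIDI heterogeneity test. A seeded
    synthetic-data module generates LD-blocked genotypes, blood-pressure
    phenotypes with medication masking, liability-model frailty deficits,
    and summary-level eQTL/GWAS scenarios, so the whole pipeline is testable
    without restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
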