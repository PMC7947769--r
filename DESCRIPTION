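Package: tetrarec
Title: Tetrasomic Linkage Analysis and Crossover Calling for Yeast Tetrad Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of meiotic recombination in diploid and
    autotetraploid budding yeast from tetrad data. Provides closed-form
    phenotype-class distributions under disomic and tetrasomic inheritance,
    maximum-likelihood estimators (with asymptotic standard errors) for the
    coefficient of double reduction and the recombination fraction between
    linked markers, prediction of per-chromosome crossover numbers from
    five-class tetrad phenotype counts, coincidence-coefficient tests of
    crossover interference with simulation-based empirical p-values, a
    configurable gametogenesis simulator for both ploidies, and reciprocal
    crossover calling from tetrad genotype matrices with marker filtering
    and short-interval merging.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
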