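Package: fluctasym
Title: Fluctuating Asymmetry Analysis of Bilateral Meristic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying developmental instability from bilateral
    meristic (count) traits. Implements the composite standardized relative
    asymmetry index (a count-scaled variant of the CFA2 composite index),
    screens that separate fluctuating asymmetry from directional asymmetry
    (one-sample t-test batteries) and antisymmetry (excess kurtosis and
    Hartigan's dip test), repeatability of double counts, Nei's unbiased
    expected heterozygosity from codominant multilocus genotypes, and the
    downstream inference chain: nested mixed models with Satterthwaite
    denominator degrees of freedom, type III multivariate tests (Wilks'
    lambda), Fisher LSD post hoc comparisons, and raw versus
    habitat-standardized Spearman correlations between population-level
    asymmetry and heterozygosity. A seeded synthetic-data generator emulates
    habitat-dependent developmental noise on left/right counts and
    Hardy-Weinberg genotypes with habitat-dependent allelic diversity, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    e1071,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
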