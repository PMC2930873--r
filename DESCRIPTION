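Package: activgps
Title: Gene-Physical-Activity Interaction Analysis with a Genetic
    Predisposition Score
Version: 0.1.0
Authors@R:
    person("EPIC", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether physical activity modifies the
    effect of a polygenic predisposition to obesity.  Builds an unweighted
    12-SNP genetic predisposition score with mean substitution of missing
    genotypes, derives a four-level physical-activity index from
    occupational class and recreational activity hours, fits
    cross-sectional and longitudinal gene-activity interaction models on
    BMI and obesity risk, quantifies attenuation of per-allele effects by
    activity stratum, and evaluates predictive discrimination via ROC
    curves.  Includes a cohort simulator that generates synthetic
    genotype-phenotype data with a configurable score-by-activity
    interaction, so that the full pipeline is testable without access to
    individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
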