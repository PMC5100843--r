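Package: hybridpred
Title: Genomic Prediction of Maize Single Crosses from Combining Ability Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction of
    single-cross (hybrid) performance in the early stages of a maize breeding
    pipeline. Simulates a two-heterotic-group (SSS/NSS) population of doubled
    haploid and recombinant inbred progenies, a sparse factorial of single
    crosses, and multi-environment field trials; applies marker quality
    control and builds additive (female, male) and dominance genomic
    relationship matrices from simple marker similarity; fits restricted
    maximum likelihood (REML) mixed models for trial analysis and
    general/specific combining ability (GCA/SCA) with genomic covariances;
    predicts untested hybrids by parental GCA(+SCA) effects or by genomic
    covariances among single crosses, including modified averaged-variance
    covariance methods and all-pairs factorial prediction; and estimates
    prediction accuracy under T2/T1F/T1M/T0 and leave-one-family-out
    cross-validation with heritability scaling and bootstrap standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
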