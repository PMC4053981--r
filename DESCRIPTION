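Package: ancestrycheck
Title: Genetic Ancestry Inference and Self-Report Concordance from Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects ancestry-informative markers from a labelled reference panel
    using informativeness for assignment, projects reference and query genotypes
    jointly with identity-by-state multidimensional scaling, classifies each query
    individual into its most similar reference superpopulation with linear
    discriminant analysis, and scores concordance of genetic ancestry against
    self-reported ethnicity and race via an expected-match mapping. Ships a
    Balding-Nichols structured-genotype simulator (discrete populations with
    tunable FST, two-way admixture, local linkage disequilibrium, missingness,
    X-chromosome genotypes, planted duplicates) so the whole pipeline is testable
    without controlled-access data, plus sample quality control: call-rate
    filtering, sex inference from X-chromosome homozygosity, and duplicate
    detection with method-of-moments identity-by-descent estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
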