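Package: tadard
Title: Gene Discovery from Inferred De Novo Variants When Parental Genotypes Are Missing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the de novo status of ultra-rare protein-truncating
    variants in affected offspring when parental genotypes are unavailable,
    using imbalanced-data ensemble classifiers (random-undersampling boosting
    and underbagging) trained on family-based cohorts with known inheritance.
    Converts the inferred likely-de-novo and likely-inherited counts per gene
    into a Random Draw Bayes factor that corrects for classifier sensitivity
    and specificity, integrates these with family-based Bayes factors, and
    selects risk genes by Bayesian FDR q-values or a Bonferroni rule.
    Includes synthetic-data generators and the null (per-family error rate)
    and power simulation studies used to validate the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rpart,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
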