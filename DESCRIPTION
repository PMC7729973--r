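Package: quartermilk
Title: Quarter-Resolved Bovine Udder Microbiota Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quarter-level bovine milk microbiota profiled by
    16S amplicon sequence-variant (SV) tables: control-aware quality filtering,
    cumulative sum scaling normalization, alpha and beta diversity with permutation
    statistics (PERMANOVA, multivariate dispersion, Procrustes/PROTEST), core
    microbiota prevalence profiles, a one-vs-rest dominance rule that flags dysbiotic
    quarters within a cow, intramammary-infection classification from colony counts,
    and culture-sequencing concordance. Includes a cow/quarter-structured synthetic
    data generator (logistic-normal-multinomial with injected dysbiosis events and
    known ground truth) so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
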