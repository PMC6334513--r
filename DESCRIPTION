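Package: detoxshift
Title: Detoxification-Gene Expression Shifts Across a Whitefly Species Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative RNA-Seq analyses of
    detoxification-gene expression across cryptic species feeding on
    multiple host plants. Provides host-range survey clustering from
    binary presence/absence matrices, maximum-likelihood (marginal) and
    maximum-parsimony ancestral host-state reconstruction under the
    two-state Mk model, negative-binomial differential-expression testing
    with median-of-ratios normalization, classification of detoxification
    genes into constitutive, plastic and shared "machinery" categories,
    a random-gene-subset clustering permutation null for
    performance-group recovery, arcsine-square-root survival statistics
    with Dunn-Sidak sequential Bonferroni comparisons, and a synthetic
    count-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
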