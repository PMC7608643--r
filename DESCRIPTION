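Package: RareCarrier
Title: Rare Pathogenic Variant Classification, Carrier Prevalence and Gene
    Constraint from Population Allele-Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an end-to-end analysis of rare pathogenic coding
    mutations in a single gene across ancestry groups using aggregate
    allele-count data of the kind exported by large exome databases:
    rule-based pathogenicity classification from in silico predictions
    (SIFT, PolyPhen-2) and ClinVar assertions, per-population heterozygous
    and homozygous carrier prevalence with sex stratification and
    chi-square heterogeneity tests, protein-domain mutation burden, and
    gene-level natural-selection constraint metrics (observed/expected
    ratios with exact Poisson confidence intervals, depletion Z-scores, and
    the probability of loss-of-function intolerance, pLI, fitted by a
    three-class Poisson mixture via expectation-maximization). A synthetic
    cohort generator with known truth labels makes every stage testable
    without access to the external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
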