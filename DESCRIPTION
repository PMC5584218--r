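Package: ptvrisk
Title: Rare Protein-Truncating Variant Case-Control Analysis and Risk
    Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rare-variant susceptibility-gene studies of the kind
    used to evaluate candidate cancer predisposition genes in large
    case-control cohorts. Covers deleterious-variant classification under
    explicit depth and allele-fraction calling rules, length-adjusted
    pre-ranked gene-set enrichment with a permutation null, carrier-based
    case-control association (crude, Mantel-Haenszel stratified and
    logistic), an admixture maximum-likelihood burden test for rare missense
    variation, power calculation for rare carrier exposures, and projection
    of relative risks onto absolute cumulative-risk curves constrained to
    population incidence, with polygenic-centile modification. A synthetic
    data module generates cohorts, read-level evidence, gene universes and
    incidence tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'synthetic.R'
    'variant-classify.R'
    'enrichment.R'
    'association.R'
    'burden.R'
    'risk.R'
    'power.R'
    'pipeline.R'
    'ptvrisk-package.R'
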