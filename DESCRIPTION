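Package: genedup
Title: Gene-Tree/Species-Tree Reconciliation and Parallel Gene Duplication Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates gene-duplication events on the branches of a species tree by
    lowest-common-ancestor (duplication-loss parsimony) reconciliation of rooted
    gene trees, applies retention filters (multi-species evidence and full
    retention in all descendant genomes), detects parallel duplications of the
    same ortholog on two focal branches with a hypergeometric overlap test, and
    provides the accompanying expression statistics: bundle-sheath/mesophyll
    preferential-expression classification and enrichment, expression-dominance
    concordance of duplicate pairs across species, and ontology-term enrichment
    with Benjamini-Hochberg correction. Includes a birth-death gene-family
    simulator with fully labelled ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
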