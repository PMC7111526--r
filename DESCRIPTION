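Package: metaboqg
Title: Quantitative Genetics of the Metabolome in Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for replicate-level metabolite profiles
    measured on a panel of inbred lines: per-metabolite variance components
    and broad-sense heritability from mixed-model ANOVA, correlation-module
    detection with module principal components, metabolite QTL (mQTL)
    mapping with Bonferroni control and gene/intergenic annotation,
    metabolome-wide association screens against organismal traits,
    integrated variant-transcript-metabolite-trait networks, and
    metabolome-based phenotype prediction by kernel BLUP (one and two
    kernels, leave-one-out cross-validation, fold-internal association
    enrichment) and elastic net. Includes a synthetic panel generator with
    recorded ground truth so the whole chain is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    igraph,
    glmnet,
    ape,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
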