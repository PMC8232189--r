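Package: ryeqtl
Title: QTL Mapping of Perenniality and Fertility in an Interspecific Rye F2 Cross
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) analysis of F2 intercross
    populations from interspecific rye (Secale cereale x Secale strictum) crosses.
    Provides ABH marker encoding and quality control, segregation-distortion and
    allele-frequency diagnostics, two-point linkage mapping with Kosambi distances,
    REML mixed models for multi-location clonal field trials (variance components,
    BLUEs, entry-mean heritability, bivariate genetic covariance), single-marker
    and cofactor-based genome scans with simpleM multiple-testing thresholds,
    explained genetic (co)variance statistics, and an epistasis scan. Includes
    closed-form models of gametophytic self-incompatibility (pollen-side Z locus,
    stigma-side S5 locus) and ring-multivalent gamete viability, together with a
    meiosis simulator that generates F2/F3 populations and plot-level phenotypes
    under these selection regimes with full ground-truth records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, QualityControl, SNP, ExperimentalDesign
RoxygenNote: 7.3.3
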