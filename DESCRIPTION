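Package: gutmarker
Title: Case-Control Gut Microbiome Analysis and Random-Forest Disease Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An ASV-level 16S rRNA case-control analysis pipeline for gut
    microbiome studies: alpha diversity estimators (observed richness,
    bias-corrected Chao1, ACE, Shannon, Simpson), rarefaction, beta-diversity
    dissimilarities (Bray-Curtis, Jaccard-binary, unweighted and weighted
    UniFrac), principal coordinate analysis, PERMANOVA and ANOSIM permutation
    tests, per-taxon nonparametric group comparisons, LDA effect size (LEfSe)
    biomarker discovery, Spearman taxon-covariate correlation maps, and a
    random-forest diagnostic model with five-fold cross-validated marker
    selection, a probability-of-disease (POD) index and ROC/AUC evaluation
    with DeLong confidence intervals. Includes a Dirichlet-multinomial
    synthetic ASV-data generator with planted ground truth so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    randomForest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vegan,
    pROC,
    phyloseq
Config/testthat/edition: 3
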