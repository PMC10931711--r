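Package: irapass
Title: Alternative Polyadenylation Analysis of Immunotherapy Response
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for alternative polyadenylation (APA) in
    tumor immunotherapy cohorts, starting from DaPars2-style PDUI
    (Percentage of Distal polyA site Usage Index) tables. Implements
    permutation-based differential 3'-UTR usage calling, construction of an
    APA-factor regulatory network with twelve-centrality hub ranking,
    correlation-score (CS) profiles, preranked gene-set enrichment with the
    pathAPAscore statistic, Cox/LASSO survival feature selection, the
    IRAPAss linear immunotherapy-response scoring system (with the
    published ten-event model packaged), and personalized-PageRank
    extraction of feature-based modules from protein-interaction networks.
    A synthetic-cohort generator with planted ground truth supports
    calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Matrix,
    survival,
    glmnet,
    pROC,
    nnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
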