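Package: sicklecyto
Title: Holographic Cytometry Morphometry and Selective Training-Set
    Refinement for Sickle Cell Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis chain for label-free screening of sickle
    cell disease (SCD) from quantitative phase images of single red blood
    cells. Generates realistic synthetic erythrocyte phase images (biconcave
    discocytes and sickled crescents), extracts 25 morphological parameters
    per cell, refines noisy donor-level training labels by a 21:1
    histogram-tail selective search that isolates critically sickled cells,
    trains logistic-regression and convolutional-neural-network classifiers
    on refined and unrefined sets, and turns per-sample predicted
    percentages into sample-level disease calls with an 8-25% decision
    model. Tidyverse-native: functions take data frames of cell records and
    return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
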