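Package: metabomiss
Title: Benchmarking Missing-Value Imputation for GC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how missing-value imputation behaves on wide-format
    metabolite abundance tables from untargeted GC-MS experiments. Simulates
    technical-replicate and biological peak tables on a log-normal abundance
    model, injects missingness under MCAR, MAR, MNAR and mixture mechanisms,
    imputes with ten single-imputation methods (zero, half-minimum, mean, kNN,
    SVD, Bayesian PCA, local least squares, random forest, ridge regression and
    quantile regression) behind one interface, and quantifies both imputation
    accuracy (RMSE, percent bias) and the bias imputation induces in downstream
    statistics (Cronbach's alpha, regression coefficients and p-values), with
    end-to-end benchmark drivers and tidy reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
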