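Package: ectradiomics
Title: Grey-Matter Radiomics for Predicting Response to ECT in Schizophrenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A leakage-controlled radiomics pipeline for predicting response to
    electroconvulsive therapy combined with antipsychotics in schizophrenia from
    structural grey-matter maps. Regions of interest are discovered on the
    training set by voxelwise two-sample t-maps with cluster-extent thresholding
    and atlas-overlap annotation; fifteen first-order histogram statistics are
    extracted per region; classification uses leave-one-out cross-validation
    with in-fold univariate filtering and LASSO-penalised logistic regression,
    replicated with a linear support vector machine; models are distilled by
    LASSO selection frequency into a fixed three-feature logistic model and
    fused with clinical covariates under variance-inflation-factor and
    coefficient-significance screening; ROC curves are compared with DeLong
    tests. A synthetic-cohort generator with planted regional effects and
    clinical tables drawn to published group summaries supports end-to-end
    evaluation when patient data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
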