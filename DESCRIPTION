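Package: choromvq
Title: Quantitative High-Definition Microvessel Imaging of Choroidal Tumors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for contrast-free quantitative
    high-definition microvessel imaging (qHDMI) of choroidal melanocytic
    tumors. Generates synthetic vascular trees and ultrafast power-Doppler
    IQ ensembles, reconstructs microvessel images via singular-value
    decomposition clutter filtering, power-Doppler formation and multiscale
    Hessian vessel enhancement, extracts twelve vessel-morphology biomarkers
    (vessel density, segment and branch-point counts, diameter, tortuosity,
    Murray's deviation, box-counting fractal dimension, bifurcation angle),
    and runs the associated group-comparison statistics: Wilcoxon rank-sum
    tests, Mann-Whitney AUC with stratified bootstrap confidence intervals,
    Firth penalized logistic regression with a structural-missingness
    linear predictor and 2-df likelihood ratio tests, pairwise-complete
    Pearson correlations, and a thickness-restricted sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    igraph,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
biocViews: Software, ImageProcessing, StatisticalMethod, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
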