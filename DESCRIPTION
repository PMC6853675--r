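Package: ActivityBootstrap
Title: Quantile-Activity Bootstrap Validation for Structure-Activity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Validation framework for structure-activity (QSAR) regression
    models that partitions data on quantiles of the activity distribution:
    models are trained on bootstrap samples of the low-activity fraction and
    tested on the high-activity extrapolation region. Provides two rank-based
    "active-rank" loss functions that score only the predicted ranks of
    high-activity molecules, a reference model zoo (ridge, linear support
    vector regression, random forest, small dense neural network) with fixed
    hyperparameters, jackknife standard errors and probability-of-optimality
    model scores, Tanimoto similarity and two-medoids clustering diagnostics,
    ChEMBL-style IC50 curation with pIC50 conversion, circular (Morgan)
    fingerprinting via Open Babel, and a synthetic-data generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    cluster,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'similarity.R'
    'fingerprints.R'
    'curation.R'
    'synthetic.R'
    'models.R'
    'utils.R'
    'resampling.R'
    'losses.R'
    'evaluation.R'
    'cli.R'
    'dataset-methods.R'
    'mlp.R'
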