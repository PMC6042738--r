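Package: eitbleed
Title: Simulation-Based Brain Haemorrhage Detection from EIT Measurement Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation study of haemorrhage detection from raw
    electrical impedance tomography (EIT) measurement frames. Builds parametric
    two-layer head models (outer tissue shell and brain) with spherical
    haemorrhagic lesions, solves the complete-electrode-model forward problem on
    structured tetrahedral meshes to produce 208-channel "skip 2" measurement
    frames from a 16-electrode ring, adds SNR-controlled Gaussian noise, and
    trains linear/RBF support vector machine and neural network classifiers with
    ROC-based operating-point selection. Seeded study runners reproduce noise,
    lesion-location, lesion-size, electrode-placement, anatomy and pooled
    benchmark experiments, reporting sensitivity, specificity, accuracy and AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
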