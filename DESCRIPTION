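Package: neuroattrib
Title: Benchmarking Attribution Methods for 3D Convolutional Mental-State Decoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to benchmark explanation (attribution) methods for deep
    mental-state decoding models on volumetric activation maps. Generates
    synthetic trial-level 3D activation volumes with planted class patterns,
    per-subject effects and smooth noise; trains small 3D convolutional
    network decoders with early stopping, hyper-parameter scoring and
    multi-seed ensembles; computes nine attribution methods (gradient,
    SmoothGrad, InputXGradient, guided backpropagation, Guided GradCam,
    integrated gradients, DeepLift, DeepLift SHAP, layer-wise relevance
    propagation) from their defining rules; aggregates attribution maps with
    a two-stage voxelwise general linear model; and scores methods on
    alignment with reference maps (Kraskov-Stoegbauer-Grassberger mutual
    information), occlusion faithfulness, and model/data randomization
    sanity checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
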