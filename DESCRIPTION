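Package: regqa
Title: Validation of Black-Box Deformable Image Registration Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance toolkit for automatic deformable image
    registration systems whose deformation functions are not user
    accessible.  Implements a four-component validation protocol: a
    digital multimodality (CT/MRI/PET) phantom with paired modification
    scenarios; relative validation of registration settings by
    post-registration similarity measures (normalized mutual information,
    mutual information, symmetric correlation ratio, correlation
    coefficient); absolute intra-modality validation with synthetic cubic
    B-spline free-form deformations and a grid-probe displacement-error
    estimator that works through an opaque image-in/image-out pipeline;
    and absolute inter-modality validation with contour overlap metrics
    (Tannimoto and Dice coefficients, mean surface distance).  Includes
    volumetric NIfTI/NRRD input and output, a minimal reference B-spline
    registrar for generating graded clinically plausible deformations,
    and mock registration systems for end-to-end protocol testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mgcv,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
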