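Package: spectre
Title: Streamline Projection of Template Color Gradients for
    Track-Weighted Imaging
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements SPECTRE-style track-weighted imaging: a smooth
    template-space color gradient is warped to subject space and summed
    along diffusion-MRI streamlines seeded in a target region, producing
    voxel-wise connectivity-pattern color maps at super-resolved grids.
    Includes diffusion tensor fitting, deterministic and stochastic
    streamline propagation by principal tensor direction or tensor
    deflection (TEND), the intraclass-distance (icd) test-retest
    reproducibility index, synthetic tensor/color phantoms with known
    ground truth, NIfTI/TCK/TRK input-output and a small command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
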