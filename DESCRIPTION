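Package: ermorph
Title: Nanoscale Morphometry of the Endoplasmic Reticulum from STED Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of superresolution (STED) images of the
    endoplasmic reticulum (ER). Detects nanoscale holes in ER sheets with a
    marker-controlled watershed and a depth-fraction border rule, computes
    per-hole shape statistics (equivalent diameter and covariance-eigenvalue
    symmetry) with nonparametric group comparisons, estimates ER tubule
    diameters by fitting line profiles with geometric label models convolved
    with a Lorentzian point-spread function, tracks seeded holes through
    time-lapse stacks, and provides a ground-truthed Poisson image simulator
    of torus-edged nanoholes plus an analytic fixed-area membrane-curvature
    budget for sheets, holes, and tubules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
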