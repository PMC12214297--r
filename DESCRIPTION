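Package: ossimetry
Title: Automated 3D Morphometry of the Middle-Ear Ossicular Chain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of the middle-ear ossicular chain (malleus,
    incus, stapes) from labeled ultra-high-resolution CT volumes. Reconstructs a
    refined, smoothed triangle mesh per ossicle (signed-distance refinement,
    topology-consistent iso-surfacing, windowed-sinc low-pass filtering),
    detects the named anatomical landmarks A-J from discrete curvature maps,
    oriented bounding boxes and principal-component axes, and derives the
    twelve standard morphometric parameters (eight distances, the
    incudostapedial joint angle, three volumes). Ships a parametric ossicle
    phantom generator with analytically known landmarks for end-to-end
    validation, the Euler-curve-energy active-contour loss used for stapes
    segmentation, and the replicate-consistency / group-comparison statistical
    workflow (ICC, normality-gated paired and independent tests, chi-square).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    RNifti,
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    car,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
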