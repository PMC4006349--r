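Package: contourctl
Title: Interactive Level-Set Segmentation by PDE Feedback Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Narrowband level-set segmentation of 2-D images and 3-D volumes
    with closed-loop feedback from user interaction. An open-loop
    region-competition PDE (global Chan-Vese mean alignment or localized
    region statistics) is augmented with a stabilizing control field built
    from accumulated signed user clicks, a nonlinear-diffusion input
    accumulator that keeps the control bounded and smooth, and an
    observer-like auxiliary PDE that estimates the user's ideal boundary.
    Includes signed-distance reinitialization by fast sweeping, synthetic
    phantoms with ground truth, a scripted simulated user, Lyapunov-style
    diagnostics, PNG/NIfTI/NRRD field I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
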