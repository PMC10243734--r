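Package: projlddmm
Title: Projective Diffeomorphic Mapping of 2D Sections onto 3D Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Registration of a dense 3D multi-contrast volume onto sparse,
    independently distorted 2D sections (projective LDDMM): diffeomorphic
    flows composed with planar or point-spread projection operators,
    wavelet-scattering contrast prediction for crossing imaging modalities,
    and Gaussian-mixture weighting of tears and background artifacts.
    Includes downstream machinery for pathology quantification: varifold
    transport of weighted particle measures, multiscale kernel resampling,
    watershed-based tangle detection, and Laplace-Beltrami smoothing of
    densities on subregion boundary surfaces. A synthetic phantom generator
    provides fully ground-truthed test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
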