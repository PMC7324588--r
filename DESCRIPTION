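Package: ctfat
Title: Density-Window Fat Volumetrics for Micro-CT Imaging of Whole Fish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the radiological quantification of adipose tissue in
    whole-body X-ray micro-computed tomography scans of fish. Implements
    ex-vivo calibration of the pure-fat attenuation value from ellipsoidal
    regions of interest, Hounsfield-unit density-window segmentation of fat
    in situ, seeded 3D isocontour delineation of the whole body with
    scanner-bed exclusion, voxel volumetrics normalised to total body
    volume, and two-group (fed versus starved) comparison by Student's
    t-test. A digital fish phantom generator with known ground-truth tissue
    labels, a parallel-beam projection/filtered-back-projection simulator,
    and NIfTI/MetaImage volume input/output support end-to-end validation of
    the pipeline without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
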