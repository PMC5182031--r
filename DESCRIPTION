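Package: fixelr
Title: Fixel-Based Analysis of White-Matter Fibre Density and Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A framework for fixel-based analysis (FBA) of diffusion MRI:
    segmentation of fibre orientation distribution (FOD) lobes into fixels
    (specific fibre populations within a voxel) with apparent fibre density
    (FD) by hemisphere quadrature, a fibre-bundle cross-section metric (FC)
    computed from the Jacobian of spatial-normalisation warps, their
    combination (FDC), angular fixel correspondence across subjects,
    fixel-wise general linear models with permutation-based family-wise
    error control, a numerical fibre-bundle phantom for validation, and
    streamline-based cropping of significant results. Fixel data are stored
    in a sparse NIfTI-based directory format interoperable with common
    viewers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    pracma,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
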