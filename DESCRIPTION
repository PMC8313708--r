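Package: fusbps
Title: Vascular Brain Positioning and Neuronavigation for Functional
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automatic vascular-fingerprint neuronavigation for functional
    ultrasound (fUS) imaging of the rodent brain. Registers 3D Power
    Doppler angiographic volumes to a pre-aligned Doppler reference by
    Mattes mutual-information maximization with a (1+1) evolution
    strategy, propagates brain-atlas labels through the composed
    transforms, targets oblique imaging planes from user markers with an
    inverse-kinematic stage solver, and quantifies residual misalignment
    with ultrasound localization microscopy (microbubble detection,
    Hungarian linking, super-resolved density/velocity maps, demons
    displacement fields). Includes SVD clutter filtering and Power
    Doppler computation, GLM activation mapping with Bonferroni
    correction, seed-based connectivity, and seeded synthetic phantoms
    (vascular trees, frame stacks, bubble movies, CBV time series) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
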