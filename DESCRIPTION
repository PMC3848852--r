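Package: tpmcmr
Title: Tissue Phase Mapping of Phase-Contrast Cardiovascular MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing of velocity-encoded (phase-contrast) cine
    cardiovascular MR of the rodent left ventricle: multi-coil phase-difference
    reconstruction with a nine-point balanced encoding scheme, polynomial
    eddy-current phase correction, papillary-anchored 32-segment myocardial
    segmentation, cardiopolar velocity decomposition, forward-backward
    Fourier trajectory tracking with dual temporal origins, Lagrangian
    circumferential strain, regional dysfunction indices, and dual
    rotated-acquisition averaging.  Includes a synthetic deforming-annulus
    phantom with closed-form velocity and strain ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'io.R'
    'kinematics.R'
    'metrics.R'
    'phantom.R'
    'pipeline.R'
    'reconstruct.R'
    'strain.R'
    'tpmcmr-package.R'
    'tracking.R'
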