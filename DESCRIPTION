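Package: widefieldGCIPL
Title: Widefield OCT Ganglion Cell-Inner Plexiform Layer Thickness Mapping
    and Ageing Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs geometrically corrected ganglion cell-inner plexiform
    layer (GCIPL) thickness grids from widefield (55 x 45 degree) optical
    coherence tomography boundary segmentations: elliptical reconstruction of
    vertical scan curvature, de-warping to the ocular nodal point, retinal-tilt
    thickness correction, axial-length-dependent transverse magnification
    correction, exclusion interpolation and fovea-disc aligned 160 x 160 grid
    averaging. Downstream statistics cover demographic multiple regression with
    a 10 percent coefficient-change elimination rule, age-bracket cluster
    analysis (within-groups hierarchical and two-step algorithms gated by
    silhouette and d-prime separability), sliding-window linear-versus-quadratic
    model comparison, and mixed-effects ageing regressions per cluster. A
    synthetic-eye generator emulates the cohort structure, spatial cluster
    model and acquisition distortions so the full cascade is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
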