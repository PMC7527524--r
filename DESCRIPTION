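Package: oculotrans
Title: Translatory Eyeball Movement from Multi-Gaze Orbital MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the positional change (translation) of the eyeball
    between gaze directions from volumetric orbital MRI. Secondary-gaze
    volumes are rigidly co-registered to the central-gaze volume using
    static (non-ocular) tissue only, the globe is extracted by seeded
    region growing, and the 3D centroid displacement is summarised as an
    in-plane distance and direction with per-eye mirroring and angle
    conventions. Includes a synthetic orbital-phantom generator with known
    globe rotation, globe translation and head motion for end-to-end
    parameter-recovery validation, and cohort-level statistics
    (one-eye-per-subject selection, normal and circular summaries,
    two-sample comparisons, biometry correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
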