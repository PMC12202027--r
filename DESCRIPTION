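Package: mocapkit
Title: Kinematic Analysis of Marker-Based Motion Capture in Freely Moving Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 3D marker trajectories recorded from freely
    moving mice with marker-based motion capture. Covers trajectory repair
    (gap filling, jitter removal), tracking-quality metrics (visibility,
    known-distance tracking error, triangulation-residual summaries),
    locomotion measures (hip-midpoint speed, locomotory-episode detection,
    surface-relative motion on treadmill and climbing wheel, head-plane
    orientation), a whole-body motion index with a noise-floor sensitivity
    sweep, context-specific limb-swing detection with per-swing kinematics,
    and tremor decomposition (band-limited power spectra, automatic tremor
    band detection, Hilbert amplitude/phase, cross-marker correlation
    matrices). Includes a seeded synthetic-trial generator with full ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
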