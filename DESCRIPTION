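Package: icefloc
Title: Quantification of Algal Aggregates in Under-Ice Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of macroscopic algal aggregates in
    upward-looking under-ice imagery from remotely operated vehicle (ROV)
    surveys. Implements green-channel threshold segmentation with frame and
    region quality control, altimeter-based pixel-to-metric registration,
    floe-fixed 3 x 3 m gridding to neutralize overlapping survey tracks, six
    spherical-equivalent biovolume and carbon estimators, Lloyd's index of
    patchiness, power-law aggregate size-distribution fitting, and
    eccentricity-based aggregate-type fractions. A synthetic under-ice scene
    and survey generator with exact ground truth makes every stage testable
    without raw dive video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
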