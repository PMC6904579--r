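Package: chitonarmor
Title: Parametric Chiton Girdle-Scale Geometry, Morphometrics and Flexible
    Armor Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generative solid modeling of chiton girdle scales from a small
    set of named shape parameters (principal-curve markers, spine extraction
    and cross-section lofting), mesh-based 3-D morphometrics of scale
    geometry (projection contours, imbrication and inclination angles,
    overlap ratios, volume and centroid), tessellation of scale arrays into
    flexible armor panels on flat, gradient and curved substrates with STL
    export for multi-material printing, and a rigid-scale kinematic bending
    model that detects inter-scale contact and the onset of geometric
    interlocking as a function of bending orientation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
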