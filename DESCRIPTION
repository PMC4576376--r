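Package: ddtag
Title: Dead-Reckoning, Energetics and Behaviour Annotation for Multi-Sensor
    Animal Tags
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for high-frequency multi-sensor biologging
    tags carrying tri-axial accelerometers and magnetometers. Imports
    delimited sensor logs, merges time-stamped positional fixes, calibrates
    magnetometers for hard- and soft-iron error by ellipsoid fitting,
    derives tilt-compensated compass headings from static acceleration,
    computes dynamic body acceleration energetics (VeDBA, ODBA) and a
    VeDBA-based speed proxy, reconstructs dead-reckoned tracks on the
    spherical earth with iterative ground-truth fix correction, classifies
    behaviour by normalized cross-correlation template matching, and
    exports all derived channels and behaviour codes into one merged table.
    Includes a synthetic-deployment simulator so every step is testable
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
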