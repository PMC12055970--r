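Package: needlecav
Title: Quantification of Cavitation Induced by Spring-Loaded Biopsy Needles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cavitation activity around spring-loaded core
    needle biopsy devices from co-registered high-speed shadowgraphy video and
    hydrophone recordings. Implements projected bubble-area estimation by frame
    binarization and rest-needle subtraction, needle-tip kinematics via
    minimum-eigenvalue feature detection and pyramidal Kanade-Lucas-Tomasi
    tracking, calibrated sound-pressure-level spectrograms with broadband-burst
    and ringing-tone extraction, and hydrodynamic characterization through the
    cavitation and Reynolds numbers. A ground-truthed synthetic-data generator
    emulates the recordings so the full pipeline is testable without the
    original datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
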