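Package: GrafAngle
Title: Automated Graf Alpha-Angle Measurement for Infant Hip Ultrasound
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated measurement of the Graf alpha-angle on coronal
    infant-hip ultrasound images, for developmental dysplasia of the hip
    (DDH) screening research. Provides a synthetic digital phantom of the
    Graf standard plane with exact ground-truth geometry, a deterministic
    classical landmark detector for the bony acetabular rim and the lower
    limb of the ilium, bone-surface ridge extraction with intensity-based
    peak screening, Hough and total-least-squares line fitting for the
    iliac baseline and bony roof line, frame-by-frame quality gating for
    video sequences, and the agreement and reliability statistics used to
    validate such systems (Bland-Altman limits of agreement, intraclass
    correlation coefficients, one-way ANOVA effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'lines.R'
    'phantom.R'
    'detect.R'
    'geometry.R'
    'pipeline.R'
    'stats.R'
    'io.R'
    'cli.R'
    'targets.R'
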