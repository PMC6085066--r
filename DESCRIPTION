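Package: crowdbox
Title: Quality Analysis of Crowdsourced Bounding-Box Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing the quality of crowdsourced bounding-box
    annotations against expert gold-standard minimum bounding boxes.
    Implements per-box precision/recall/F1 scoring with best-match
    assignment and conflict zeroing, a synthetic scene and crowd-annotator
    simulator for plant-phenotyping style tassel images, linear
    mixed-effects analyses of annotator performance (group contrasts,
    fatigue regression on log completion time, per-image BLUPs), and a
    bag-of-visual-words + support-vector-machine pipeline that trains
    per-annotator tassel classifiers and evaluates them as the mean of the
    true positive and true negative rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    e1071,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
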