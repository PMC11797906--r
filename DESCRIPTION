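Package: periobone
Title: Alveolar Bone Loss Quantification and Periodontal Prognosis from
    Panoramic Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of dental panoramic radiographs
    downstream of tooth and cemento-enamel junction (CEJ) segmentation:
    image enhancement (unsharp masking, histogram equalization, 3x3
    Gaussian smoothing), per-tooth landmark geometry (CEJ, alveolar bone
    crest, root apex) from segmentation polygons, percentage alveolar
    bone loss with the 2 mm biologic-width correction, per-tooth
    periodontal prognosis per the Thai Association of Periodontology
    bands, and a detection-evaluation suite (IoU matching, confusion
    matrices, precision/sensitivity/specificity/accuracy/F1, average
    precision at IoU 0.5).  A synthetic-radiograph generator with an
    oracle detector provides fully known ground-truth geometry so the
    whole pipeline is testable without clinical data.  Reads and writes
    LabelMe JSON polygons, YOLO-style normalized polygon labels, and
    CSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    png,
    polyclip,
    purrr,
    readr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
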