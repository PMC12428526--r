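Package: zooscanr
Title: Population Structure and Vertical Distribution of Planktonic
    Copepods from Plankton-Scanner Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline from scanned plankton images (or
    EcoTaxa-style per-object detection tables) to population structure:
    calibrated object area, equivalent spherical diameter (ESD) and
    spherical biovolume; depth-stratified abundance and biovolume
    profiles integrated over the 0-1,000 m water column; vertical
    distribution composition and weighted mean depth; 0.1-mm ESD
    size-frequency histograms and size-by-depth matrices; Gaussian
    copepodite-stage assignment from per-stage ESD references; and
    day/night vertical-migration metrics distinguishing diel from
    seasonal migrants. Includes a synthetic-data generator that emulates
    stratified day/night net tows across seasons with aliquot
    subsampling, plus a ground-truthed scan-image simulator for the
    segmentation stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
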