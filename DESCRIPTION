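Package: eyescreen
Title: Probability-Based In Vitro Eye Irritation Screening from
    Micropatterned Cell Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and digitizes high-content screening readouts from
    micropatterned human corneal epithelial cell assays and turns them into a
    probability-based eye-irritation index. Includes a synthetic-data
    generator for micropattern chip images, calcium time-lapse stacks and
    binary dose-response tables with known ground truth; ROI-grid
    registration, nuclei segmentation and per-cell intensity and trace
    measurement; binarization of apoptosis (caspase-3/7) and TRPV1/calcium
    responses at the cell and micropattern level; and binary logistic
    dose-response fitting with IC50, Wald confidence bands, and the union
    probability combining apoptosis and nociceptor activation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
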