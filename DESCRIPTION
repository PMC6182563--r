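Package: mycomorph
Title: Quantitative Morphometry of Mycelial Objects in Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An edge-based image-analysis pipeline for tracking the
    morphological evolution of filamentous fungi in submerged culture.
    Micrographs are median-smoothed, Sobel edge-enhanced and segmented into
    labeled mycelial objects; per-object size and shape descriptors
    (projected area, mean and maximum Feret diameter, elongation, roughness
    or solidity, circularity, and the dimensionless morphology number) are
    computed on a physical micrometer scale, debris is removed by size and
    shape filters and areas of interest, objects are partitioned into two
    size classes, and per-timepoint statistics with Student-t confidence
    bands are produced. A seedable synthetic scene generator renders
    phase-contrast-like micrographs of spores, agglomerates, hairy pellets,
    clumps and mineral microparticle debris with ground-truth masks, so the
    whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
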