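Package: mnctess
Title: Maximal Nucleus Clustering and Renyi Entropy Profiling of
    Tessellated Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tessellates 2D grayscale images (including single slices of
    fMRI volumes) into bounded Voronoi regions seeded at pixels whose
    quantized gradient-orientation angle is unique in the image, detects
    maximal nucleus clusters (regions with the highest number of
    edge-sharing neighbours), compares the information content of
    cluster and non-cluster polygon sets with Renyi entropy over a beta
    sweep, and matches cluster descriptors across temporal frame
    sequences, including antipodal frame pairing on the temporal circle.
    Ships a seeded synthetic-image generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
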