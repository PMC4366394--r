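Package: ccmorph
Title: Developmental Morphometry of the Corpus Callosum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying growth of the corpus callosum on midsagittal
    images from infancy to early adulthood: geometric Witelson parcellation of
    binary midsagittal masks into the seven classical subregions (rostrum,
    genu, rostral body, anterior midbody, posterior midbody, isthmus,
    splenium), robust locally weighted (lowess) developmental trajectories
    with monthly growth-change rates and growth-peak detection, mixed-design
    repeated-measures cohort statistics with Tukey-Kramer post hoc
    comparisons and rank-based sex contrasts on brain-normalised ratios, and
    a seeded synthetic-cohort and mask generator for validating every stage
    without access to scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    png,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
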