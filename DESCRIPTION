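Package: sipstats
Title: Statistical Image Properties and Aesthetic Rating Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how objective statistical image properties
    (SIPs) relate to aesthetic judgments of abstract images. Synthesizes
    colored random-phase stimuli with prescribed Fourier spectral slopes,
    computes a battery of SIPs (gradient complexity, PHOG self-similarity
    and anisotropy, edge-orientation entropies, filter-bank variance
    measures, CIELab/HSV color statistics, mirror symmetry, spectral slope),
    reduces SIP sets by exhaustive best-subset regression and collinearity
    pruning, fits standardized-coefficient rating models, measures squared
    Mahalanobis distance to a reference corpus in SIP space, clusters
    raters by preference profiles, and generates complete synthetic rating
    studies with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    png,
    tiff,
    jsonlite,
    cluster,
    withr,
    EBImage,
    generics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
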