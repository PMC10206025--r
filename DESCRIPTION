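Package: memotopy
Title: Population Receptive Field Mapping and Inverted Encoding Models for
    Spatial Working Memory fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how retinotopically organised visual structures
    encode locations held in spatial working memory. Implements Gaussian
    population receptive field (pRF) estimation from bar-sweep mapping runs
    (coarse grid search, hemodynamic response fitting, fine nonlinear
    refinement), field-of-view and size-eccentricity summaries, univariate
    delay-period analyses of memory-guided saccade tasks (RF-in versus RF-out
    voxel wedges), a spatial inverted encoding model over polar angle with
    nine squared-cosine channels, representational fidelity metrics with
    permutation and bootstrap inference, Fisher-Lee circular correlation
    between pRF and encoding-model tuning, and a synthetic BOLD generator with
    known ground truth so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
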