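Package: growscreen
Title: Dynamic Colony-Fitness Screening from Time-Lapse Plate Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies colony growth from time-lapse images of high-density
    mutant arrays and nominates treatment-responsive strains. Plate photographs
    are smoothed with anisotropic diffusion, colonies are segmented by
    half-mode-max thresholding on a user-anchored grid, and summed pixel
    intensities are spatially corrected for border overgrowth and plate-scale
    gradients. Per-colony trajectories are smoothed with robust LOWESS,
    endpoint-normalized, and compared to the plate median reference curve to
    yield the signed dynamic-growth metric lagVstall alongside endpoint colony
    fitness. Replicate-level metrics are robust Z-scored (median absolute
    deviation one), compared between conditions with pooled two-sample t-tests,
    corrected with Storey q-values, and nominated strain sets are tested for
    hypergeometric gene-set enrichment. A fully labeled synthetic-plate
    simulator (logistic growth with lag, stall, and treatment-response classes,
    replicate noise, spatial bias, and optional image rendering) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    tiff,
    yaml,
    EBImage,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
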