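Package: cdlkit
Title: Cochlear Duct Length Estimation from Lateral-Wall Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cochlear duct length (CDL) for cochlear-implant
    electrode planning from three-dimensional lateral-wall point clouds and
    from basal-turn landmark measurements. Implements canonical modiolar-frame
    alignment, angular unwrapping and spline arc length for segmented point
    clouds; the A-value (Escude) and elliptic-circular (A/B-value) CDL
    formulas with organ-of-Corti and resolution corrections; insertion-angle
    based reference CDL and cochlear-coverage predictions; simulation of
    electrode-array insertion along a cochlear trajectory; a parametric
    synthetic-cochlea generator with ground truth, CT-like voxel phantoms and
    threshold segmentation; and the method-comparison statistics used to
    benchmark estimators (one-way ANOVA with Dunnett contrasts against a
    reference, Pearson and dependent-correlation comparison, and two-way
    random-effects intraclass correlation with reliability banding).
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
    igraph,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    lme4,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
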