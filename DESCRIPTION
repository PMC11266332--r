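Package: petiq
Title: PET Image Quality Metrics and Injected-Activity Reduction Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how far the injected activity of a PET
    radiotracer can be reduced while preserving diagnostic image quality.
    Provides a digital NEMA image-quality phantom and synthetic-patient
    simulator with Poisson count noise, Gaussian point-spread blurring,
    binomial count thinning (to emulate reduced injected activity) and a
    beta-parameterised noise-suppression surrogate for penalised
    reconstruction; volume-of-interest construction (spheres, cylinders,
    half-maximum lesion isocontours) and statistics; standard image-quality
    metrics (contrast recovery, background variability, contrast-to-noise
    ratio, liver noise, lesion signal-to-noise and signal-to-background
    ratios); reader-study statistics (mean visual scores, Cohen's kappa,
    two-way mixed absolute-agreement single-rater intraclass correlation,
    lesion detectability); and an orchestrated two-step procedure that
    selects an optimal penalisation factor per activity-reduction level and
    issues a final reduction recommendation.
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
    lme4,
    multcomp,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
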