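Package: fwshells
Title: Perilesional Free-Water Imaging Analysis for Subcortical Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis of free-water diffusion MRI around
    subcortical brain lesions. Simulates single-shell diffusion-weighted
    volumes over synthetic mirror-symmetric phantoms with Rician noise, fits
    the two-compartment free-water elimination model (free-water fraction and
    free-water-corrected tissue tensor, FA-T) by vectorized constrained
    Levenberg-Marquardt, constructs concentric 2-mm perilesional tissue shells
    with contralateral mirroring, ventricle subtraction and white-matter
    filtering, normalizes region means to the contralateral hemisphere, and
    runs the longitudinal statistics layer: per-region one-sample t-tests,
    linear mixed-effects models with crossed subject and location random
    intercepts, Tukey post-hoc timepoint contrasts, Spearman correlations,
    adjusted regressions and power estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
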