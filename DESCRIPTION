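Package: morphoagree
Title: Muscle Biomarkers and Method Agreement for Morphofunctional Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives whole-body muscle mass and fat-free mass biomarkers from
    computed tomography (CT), bioelectrical impedance analysis (BIA), and
    nutritional ultrasound (US) measurements using published prediction
    equations; applies covariate-conditional diagnostic rules for muscle
    atrophy, myosteatosis, dynapenia, sarcopenia, and GLIM malnutrition; and
    quantifies intra- and inter-technique agreement with Bland-Altman limits
    of agreement, Lin's concordance correlation coefficient, Cohen's kappa,
    and normality-gated comparisons of central tendency. A synthetic-cohort
    generator with a latent-muscularity factor supports end-to-end testing
    and parameter-recovery experiments without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    yaml,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
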