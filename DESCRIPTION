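Package: epiage
Title: Epigenetic Clocks and Age Acceleration for Captive Baboon Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds reduced-representation bisulfite sequencing (RRBS) based
    epigenetic clocks for olive baboons (Papio anubis) and relates the
    resulting age-acceleration estimates to behavioral indicators of aging.
    Ingests per-CpG methylation calls in Bismark coverage format, applies a
    site-exclusion cascade (polymorphic positions, mean methylation level,
    mean depth of coverage, missingness), fits a sparse elastic-net age
    predictor with leave-one-out cross-validated age estimates, derives two
    delta-age measures (raw difference and regression residual) with
    acceleration/deceleration categories, and fits hierarchical regressions
    and univariate ANOVAs linking (epigenetic) age to walking speed and fine
    motor performance. A calibrated synthetic-data generator reproduces the
    statistical structure of such cohorts so the whole pipeline is testable
    without access to primate data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
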