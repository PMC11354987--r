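Package: thyrocentiles
Title: Age- and Sex-Specific Centile Standards for Thyroid Hormones and
    the fT3/fT4 Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and application of pediatric reference
    standards (centile charts) for TSH, free T3, free T4, and the
    fT3/fT4 ratio over ages 0-29 years.  Provides the Box-Cox power
    exponential (BCPE) distribution family used in GAMLSS-style
    quantile modelling, penalized maximum-likelihood fitting of
    age-varying distribution parameter curves, cohort cleaning rules
    for thyroid reference populations, SI/conventional unit conversion
    for thyroid laboratory values, percentile-threshold screening of
    individual patients for thyroid-hormone-resistance patterns
    (MCT8/THRA/SECISBP2-like), and a calibrated synthetic-cohort
    generator emulating the age and sex structure of large German
    pediatric surveys for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
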