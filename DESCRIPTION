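Package: lifespanvol
Title: Lifespan Trajectories and Normative Centiles of Subcortical Brain
    Volumes from Multi-Site MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of age trajectories of subcortical brain
    volumes pooled across many MRI acquisition sites. Provides multi-site
    quality control (complete-case filtering and Mahalanobis outlier
    exclusion), per-site intracranial-volume adjustment, parametric
    empirical-Bayes (ComBat) site harmonization, fractional-polynomial age
    trajectory estimation with closed-test model selection and
    site-clustered standard errors, age-band inter-individual variability
    statistics with omnibus variance tests and random-effects meta-analysis
    of log standard deviations, and LMS (Box-Cox Cole-Green) normative
    centile curves selected by generalized AIC. A bundled multi-site
    synthetic cohort generator emulates the statistical structure of large
    lifespan neuroimaging compilations so the whole pipeline is testable
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    sandwich,
    car,
    metafor
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse,
    withr
Config/testthat/edition: 3
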