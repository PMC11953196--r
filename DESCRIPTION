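Package: piin
Title: Photoreceptor Integrity Index for Full-Thickness Macular Holes
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of photoreceptor loss at the edge of
    full-thickness macular holes from en-face optical coherence tomography
    (OCT). Implements the three-step area protocol (total hole area, luminal
    area, photoreceptor-remnant area), cohort min-max normalization, and the
    bounded Photoreceptor Integrity Index (PIIN); an automated annulus
    segmentation pipeline for en-face rasters; a synthetic phantom and cohort
    generator (Gaussian copula with quantile-matched margins) for fully
    reproducible evaluation; and the associated statistical toolkit
    (descriptives, Spearman correlation with listwise deletion, Wilcoxon
    tests, Jarque-Bera normality, univariate regression, and Lin's
    concordance correlation coefficient with confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
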