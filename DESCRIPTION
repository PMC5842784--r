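Package: metcovnet
Title: Metabolic Covariance Brain Networks from Regional PET Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds group-level metabolic brain networks from regional
    FDG-PET standardized uptake value ratios (SUVR) by correlating
    regional uptake across subjects, and quantifies global, regional and
    intrinsic-connectivity-network (ICN) metabolic correlation strength
    on the Fisher-Z scale. Provides cohort stratification by amyloid
    (PIB index) and ApoE e4 status with demographic matching, edge-level
    ANOVA with Tukey HSD, permutation tests of regional strength
    differences with empirical confidence intervals, grey-matter
    constrained Chebyshev geodesic distances for spatial-proximity
    control, and a seeded synthetic cohort generator with planted
    covariance regimes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    optparse,
    RNifti
Config/testthat/edition: 3
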