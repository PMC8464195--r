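Package: hptlcauth
Title: Chemometric Detection of Sugar-Syrup Adulteration in Honey from
    HPTLC Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting post-harvest sugar-syrup adulteration of
    honey from high-performance thin-layer chromatography (HPTLC) data.
    Combines per-sample sugar quantifications (fructose, glucose, maltose,
    sucrose) with multi-channel organic-extract band profiles (Rf versus
    intensity) into a single feature matrix, expands small plate studies by
    a run-to-run variability augmentation model (Rf drift plus calibrated
    Gaussian intensity noise), and runs the full multivariate suite:
    hierarchical clustering, k-means with elbow selection, density-based
    clustering (DBSCAN), principal component analysis, principal component
    and partial least squares regression with RMSECV component selection,
    and a multi-class feed-forward neural classifier evaluated by k-fold
    cross-validation. A synthetic study generator reproduces the canonical
    68-sample design (2 honeys, 6 syrups, 60 blends at 10-50% w/w) so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
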