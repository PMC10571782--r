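Package: herddens
Title: Grazing Density and Herding Proximities from UAV Herd Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatiotemporal distribution of free-grazing
    livestock herds from georeferenced aerial snapshots. Detects animals in
    RGB imagery by colour and physical body-size filtering, geolocates them
    through image extent files, and estimates a grazing-density (GD) surface
    with a re-normalised triangle-kernel density estimator whose per-animal
    plane integral is one animal-hour, scaled by pasture area, annual grazing
    days and daily sampling frequency. Derives a dispersion index (DI) by
    threshold segmentation of the GD surface, measures herd-to-campsite
    proximities with in-campsite exclusion and seasonal grouping, and runs the
    accompanying statistical battery (Shapiro-Wilk, quadratic trend fits,
    one-way ANOVA with Duncan's multiple range post test, independent
    t-tests). A seeded herd-movement simulator and aerial-image renderer
    provide ground-truthed inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mgcv,
    yaml,
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
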