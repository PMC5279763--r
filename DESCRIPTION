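Package: copbalance
Title: Time-Resolved Balance Measures from Center-of-Pressure Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies postural balance from force-plate center-of-pressure
    (CoP) trajectories recorded during dynamic, game-like weight-shifting
    tasks. Computes eleven time-resolved measures per trial - windowed
    dispersion statistics (SD, RMS, coefficient of variation) of the
    fluctuation from the mean, their distance-travelled-normalized variants,
    turbulence intensities of instantaneous speed, and a discrete three-point
    circumcircle curvature - and aggregates them into a trial-by-measure
    matrix. Provides cubic-spline resampling and end-trimming preprocessing,
    a seeded synthetic-cohort generator emulating lateral sway of younger and
    older movers, a group-comparison battery (Shapiro-Wilk routed Welch t or
    Mann-Whitney U tests, Bonferroni correction, kernel-density overlapping
    coefficients), principal component analysis with per-variable
    contributions and confidence ellipses, and the accompanying exploratory
    visualizations (stabilogram heat maps, violin plots, parallel
    coordinates, biplots, scatter/correlation matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
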