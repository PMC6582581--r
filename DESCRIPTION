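Package: dosemass
Title: Dose-Volume and Dose-Mass Histogram Analysis for Breath-Hold
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("dosemass", "maintainers", email = "dosemass@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing free-breathing and deep-inspiration
    breath-hold (DIBH) radiotherapy of the left breast at the voxel level.
    Computes cumulative dose-volume (DVH) and dose-mass (DMH) histograms and
    their scalar metrics (Dmean, Vx, Mx) from CT, dose and structure data;
    converts Hounsfield units to mass density via a calibration table;
    quantifies lung expansion between breathing states with multi-resolution
    B-spline deformable image registration and deformation-vector-field
    statistics; generates paired FB/DIBH thorax phantoms with known
    ground-truth deformation, mass-conserving lung density change and
    tangential-field dose; and aggregates per-patient metrics into cohort
    tables with Wilcoxon tests, DVH-DMH regression thresholds and Spearman
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
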