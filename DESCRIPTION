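Package: periclim
Title: Periconceptional Temperature Anomalies and Later-Life Metabolic Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for linking day-specific ambient temperature
    anomalies to individuals' estimated conception windows and estimating
    their association with adult metabolic outcomes. Fits per-station
    day-of-year climatologies by fourth-degree polynomial regression,
    computes daily temperature deviations, interpolates them to birthplaces
    by inverse-distance weighting over Vincenty (WGS84) distances within a
    200-km radius, averages them over five periconceptional windows anchored
    at the estimated date of conception (birth minus 266 days), and fits
    linear and logistic regressions with area-by-birth-month fixed effects,
    area-clustered standard errors and Holm multiple-testing correction.
    Includes a synthetic station-network and cohort generator with known
    ground truth for parameter-recovery, confounding-removal and
    measurement-error attenuation experiments, plus scenario translations of
    coefficients into interpretable magnitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
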