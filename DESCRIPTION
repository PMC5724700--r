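Package: reachmetab
Title: Reach-Scale Stream Metabolism from Aquatic Eddy Covariance and
    Bottle Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying reach-scale stream metabolism from
    high-frequency aquatic eddy-covariance (AEC) measurements and in situ
    bottle incubations. Processes raw 3-D velocity and dissolved oxygen
    time series into quality-controlled benthic oxygen fluxes (despiking,
    double rotation, Reynolds decomposition by linear detrending,
    time-shift correction, oxygen storage correction, friction velocity
    and footprint diagnostics), estimates water-column volumetric rates
    from light/dark incubations, combines both compartments into daily
    and seasonal budgets of ecosystem respiration (ER), gross primary
    production (GPP) and net ecosystem metabolism (NEM), fits
    photosynthesis-irradiance responses, and relates NEM to streambed
    light and hydrological connectivity via windowed base-flow ratios.
    Includes seeded synthetic-data generators for turbulence, incubation
    and hydrograph inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
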