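Package: swampdendro
Title: Tree-Ring Chronologies, Hydroclimate-Growth Correlations, and
    Carbon-Isotope Water-Use Efficiency for Wetland Conifers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds standardized tree-ring chronologies for subtropical
    wetland conifers (age-dependent spline detrending, autoregressive
    prewhitening, Tukey biweight robust averaging) together with the
    quality statistics used to judge them (mean sensitivity, series
    intercorrelation, expressed population signal).  Relates chronologies
    to monthly climate and water-depth series through correlation
    functions with stationary-bootstrap confidence intervals, converts
    ring widths to basal area increments for age-class-isolation and
    spatial trend analyses, and derives intrinsic water-use efficiency
    from wood delta-13-C through the Farquhar discrimination model under
    a dated atmospheric CO2 history.  A seeded synthetic-data module
    generates ring-width, climate, water-level, spatial and isotope
    datasets with the statistical structure the analyses assume, so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
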