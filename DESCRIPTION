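Package: heatshock
Title: Heatwave Detection, Occupational Heat Stress and Economy-Wide
    Labour-Productivity Impacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying labour-productivity
    losses caused by heatwaves and propagating them through a multi-region,
    multi-sector computable general equilibrium (CGE) economy. Detects
    regional heatwaves with the TX90p percentile rule, computes the Wet Bulb
    Globe Temperature (WBGT) heat-stress index in sun and shade variants from
    hourly meteorology, converts WBGT into hourly workability via the ISO,
    NIOSH and Hothaps exposure-response functions by workload class,
    aggregates population-weighted regional-sectoral losses into
    annual-equivalent productivity shocks with quarterly seasonal weighting,
    and solves a compact CES/Armington/CRESH general-equilibrium model
    calibrated on balanced toy social accounting matrices to report GDP and
    gross-value-added impacts with sectoral decomposition. Includes synthetic
    generators for hourly gridded meteorology with injectable hot spells,
    population grids, region polygons and balanced toy economies, plus
    empirical quantile-mapping bias correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
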