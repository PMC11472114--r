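Package: vulnmap
Title: Small-Area Climate-Health Vulnerability and Hazard Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds a hierarchical social-vulnerability index for small
    census areas (rank normalisation, exponential transformation and
    weighted aggregation of metrics into sub-domains, domains and an
    overall 0-100 index), computes per-area flood and heat exposure from
    gridded hazard fields and building locations (proportion of buildings
    flooded above a depth threshold; building-weighted summer temperature
    and warm-day exceedance), ranks areas into deciles and terciles, and
    cross-classifies vulnerability against hazard exposure on a 3x3 risk
    matrix for mapping. Includes a synthetic study-region generator
    (areas, census counts with a planted latent vulnerability factor,
    buildings, a channel-decay flood-depth grid and daily temperature
    grids with an urban-heat-island component) so the full pipeline runs
    and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
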