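Package: cobenefits
Title: Health Co-Benefits, Valuation, and Environmental-Justice Analysis
    of Decarbonization Scenarios
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tract-level assessment of the air-quality health co-benefits of
    greenhouse-gas mitigation scenarios. Aggregates gridded annual-mean PM2.5
    concentration fields to census tracts, computes avoided premature
    mortality with log-linear concentration-response functions pooled by
    inverse-variance (fixed and DerSimonian-Laird random effects), monetizes
    avoided deaths with a value of a statistical life, allocates economy-wide
    mitigation costs per capita, and evaluates the equity of the benefit
    distribution with Lorenz curves, the Suits Index (statewide and by
    county), and a dispersity statistic over vulnerability-ranked tracts.
    Includes a synthetic-region generator with tunable coupling between
    vulnerability and benefit so the full pipeline runs at desk scale, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
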