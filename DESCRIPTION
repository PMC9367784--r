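Package: cattleGHG
Title: Life-Cycle Greenhouse-Gas Inventory for Beef Cattle Breeding Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds annual CO2-equivalent greenhouse-gas inventories for beef
    cattle herds under an ecological-cycle (integrated crop-livestock, silage
    feed, full manure return) and a conventional (common corn, partial manure
    return, open straw burning) breeding model. Implements IPCC Tier-1 style
    emission-factor calculations for enteric fermentation CH4, manure-management
    CH4 and N2O (direct, volatilization and leaching pathways), soil N2O from
    fertilizer and manure application, feed-production and corn-planting CO2,
    and crop-residue open-burning emissions, aggregated with GWP100 factors.
    Includes scenario configuration files, per-process and per-gas reporting,
    scenario comparison, one-at-a-time sensitivity elasticities, Monte-Carlo
    uncertainty propagation, and a synthetic-scenario generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    tibble,
    dplyr,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
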