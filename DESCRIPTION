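Package: emsloc
Title: Ambulance Location Planning from Census-Area Demand Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning emergency-medical-service (EMS) ambulance
    locations from small-area census demand. Provides a seeded synthetic-city
    generator (road network, Voronoi census areas, demographics, candidate
    stations, case points), stepwise ordinary-least-squares demand regression,
    Hamilton-Perry cohort-change-ratio population projection, shortest-path
    origin-destination matrices on road networks, a grouping genetic algorithm
    for the case-weighted p-median location problem with an exact
    small-instance oracle, and evaluation of response times, catchments and
    station workload under current and optimised deployments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
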