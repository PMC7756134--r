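Package: thickair
Title: Summit Air Pressure and Oxygen Availability on Mt. Everest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs summit-level air pressure from bracketing
    pressure-level fields via the local vertical gradient of log pressure,
    converts pressure to physiological quantities (inspired oxygen partial
    pressure, VO2max, apparent elevation, sustainable climbing rate),
    detects and composites extreme low-pressure events with upper-level
    wave transit-time estimates, quantifies trends and climate-warming
    sensitivities of summit pressure (Theil-Sen estimates, ensemble
    30-year-mean regression), and joins mountaineering ascent catalogs to
    the hourly reconstruction. Includes a synthetic-data generator that
    emulates the statistical structure of the reanalysis, weather-station,
    climate-ensemble, and ascent-catalog inputs so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
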