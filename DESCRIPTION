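Package: ecoclimex
Title: Semi-Mechanistic Ecoclimatic Niche Modelling with Irrigation Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A weekly-timestep climatic niche model for invasive-species
    risk mapping. Monthly climate normals are expanded to a 52-week year
    and driven through trapezoidal temperature and soil-moisture response
    indices, a 100 mm single-bucket soil hydrology with spin-up, annual
    cold/heat/dry/wet/hot-wet stress accumulation, a degree-day generation
    gate, and the Ecoclimatic Index (EI, 0-100) with the standard
    suitability classes. Ships the four published parameter presets for
    the European wasp (Vespula germanica), a summer top-up irrigation
    scenario, composite irrigated/natural risk grids, weekly phenology
    export, and a synthetic-climate generator covering contrasting
    climate archetypes so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
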