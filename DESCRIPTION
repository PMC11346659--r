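Package: barriersim
Title: Biogeomorphic Cellular Simulation of Barrier Island Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Slab-lattice cellular simulator of barrier island evolution under
    sea-level rise. Four coastal plant species (two dune grasses, a marsh
    grass, and a woody shrub) grow, compete, and disperse on a regular grid
    while sediment moves by wind (aeolian slab transport), gravity
    (angle-of-repose avalanching), and Bruun-type shoreline recession driven
    by quadratic sea-level-rise scenarios; every sediment process is
    attenuated by local effective vegetation cover. Includes a synthetic
    island and wind-climate generator, ESRI ASCII raster input/output,
    per-transect shoreline regression reporting, and multi-decade scenario
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
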