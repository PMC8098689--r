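Package: humitect
Title: Humidity-Template Construction Simulator for Termite-Inspired Building
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled environment-agent simulator of humidity-templated
    collective construction, modelled on mound-building termites. A 2D
    lattice humidity field (explicit finite-difference diffusion, ambient
    exchange, evaporation from a wet substrate) is coupled to a single
    building agent that carries blocks forward along a tunnel, samples
    relative humidity ahead of itself, and deposits its block against
    existing structure wherever humidity falls below a threshold, dripping
    water as it moves. Includes an experiment runner for still-air, fan and
    dry treatments with seeded replication, trigger-distance analysis with
    two-sample t-tests, trigger-point maps, and YAML-configured trials with
    full provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    png,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
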