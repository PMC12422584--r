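Package: capsakinesis
Title: Chemokinesis Analysis and Predator-Prey Simulation for Crawling Protists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chemokinesis (concentration-dependent speed
    modulation without directional bias) in crawling cells, built around the
    predation ecology of the filose amoeba Capsaspora owczarzaki hunting
    schistosome sporocysts. Provides generators for synthetic persistent-random-
    walk cell tracks with tracking artifacts, saturating dose-response readings,
    and calcium-indicator fluorescence traces; the track-filtering and velocity
    statistics used to measure chemokinesis and chemotaxis from time-lapse
    tracking tables; Hill-curve dose-response fitting with EC50 estimation; a
    finite-difference solver for the diffusing chemo-effector field exuded by
    prey; and an agent-based Monte-Carlo simulation of irreversibly-attaching
    predators with and without chemokinesis, reporting attachment fractions and
    cumulative residence times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
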