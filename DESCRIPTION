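Package: glottorisk
Title: Global Language Extinction Risk: Components, Thresholds, Drivers and
    Threat Categories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for macroecological analysis of language
    extinction risk. Computes per-language risk components (range size,
    speaker population size, speaker growth rate from Poisson trend models
    of irregular survey series), estimates threshold relationships among
    them with segmented (breakpoint) regression compared against null,
    linear and quadratic alternatives by AIC, grids language ranges onto a
    Behrmann equal-area projection, infers spatial drivers with
    simultaneous autoregressive (SAR) error models and Akaike-weight
    multimodel averaging, and categorizes languages against IUCN Red List
    criteria (A3, B1, C1, D1, D2) with hotspot and extinction-filter
    mapping. Ships a synthetic-world generator emulating the structure of
    global language range and speaker time-series databases, so the whole
    pipeline is testable end to end without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
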