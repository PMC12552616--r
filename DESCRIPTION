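Package: porevoc
Title: Covalent Nanopore Sensing of Volatile Aldehydes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-channel current recordings from
    engineered alpha-hemolysin nanopores that detect aldehydes through reversible
    hemithioacetal formation at a single engineered cysteine. Provides a
    continuous-time Markov simulator for two-level (open pore / covalent adduct)
    traces, threshold-based idealization into blockade events with residual-current,
    duration and noise features, maximum-likelihood dwell-time kinetics with
    dead-time correction and hydration-equilibrium correction of association rate
    constants, event classification for multi-aldehyde mixtures, and ratiometric
    concentration estimation from event frequencies. Packaged parameter sets
    describe four engineered nanopore variants and ten aldehyde analytes.
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
    data.table,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
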