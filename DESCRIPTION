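Package: seqpev
Title: Sliding-Window Explained-Variance Analysis of Sequential-Behavior
    Spike Trains
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for single-unit recordings
    obtained during a two-sequence serial-choice task with uncued block
    transitions. Provides a behavioral task simulator with a pseudorandom
    block-termination criterion, an inhomogeneous-Poisson spike-train
    generator with known multiplicative tuning to task factors, event-aligned
    binning, one-way and two-way ANOVA effect sizes (omega-squared and
    partial omega-squared, the percent-explained-variance statistic),
    permutation significance tests, per-neuron selectivity classification,
    population PEV time courses, information-latency extraction, and
    outcome/switch analyses, together with a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'anova-effects.R'
    'task-sim.R'
    'behavior-metrics.R'
    'synthetic-ephys.R'
    'windows-alignment.R'
    'pev-internal.R'
    'selectivity.R'
    'timecourse-population.R'
    'io-formats.R'
    'pipeline.R'
    'seqpev-package.R'
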