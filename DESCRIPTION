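Package: meltplex
Title: Discrete-Melt Multiplex Digital PCR Analysis and Simulation
Version: 0.1.0
Authors@R: person("meltplex", "developers", role = c("aut", "cre"),
    email = "meltplex@example.org")
Description: Analysis pipeline for discrete-melt multiplex digital PCR
    (mdPCR) with melt-based hairpin probes: per-partition melt-window
    fluorescence ratios, rolling-window baseline normalization, threshold
    calling of up to 12 probes across 4 optical channels, Poisson absolute
    quantification with 95% confidence intervals, allele fractions,
    limit-of-blank / limit-of-detection statistics, replicate precision and
    inter-laboratory concordance. Includes a ground-truthed simulator of
    partition fluorescence (Poisson target loading plus a phenomenological
    hairpin-melt model) so the whole pipeline can be exercised and validated
    without instrument data, and a command-line interface for end-to-end
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
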