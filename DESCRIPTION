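Package: swingboat
Title: Sleep, Exercise and Survival Analysis for Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing Drosophila Activity Monitor (DAM) recordings
    from rotating-tube ("swing boat") exercise experiments. Reads and writes
    Trikinetics-style monitor files, scores sleep from the five-minute
    inactivity rule, classifies sleep bouts into fragmented (short) and
    consolidated (long) sleep, calls deaths from terminal immobility,
    estimates Kaplan-Meier survival with log-rank group comparisons,
    quantifies per-stimulus exercise success during rocking sessions, builds
    ZT-aligned actograms and average daily activity profiles, and compares
    genotype or treatment groups with living-only daily averaging. A
    stochastic simulator of per-minute beam-crossing series (circadian
    bimodal activity, siesta, two-state sleep/wake bouts, nocturnal spiking,
    exercise responses, mortality) lets the entire pipeline run without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
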