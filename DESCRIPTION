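Package: epgtools
Title: Simulation, Event Detection and Phenotype Classification for
    Electropharyngeogram Recordings
Version: 0.1.0
Authors@R:
    person("EPG", "Tools Developers", email = "epgtools@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of electropharyngeogram (EPG) recordings
    of the Caenorhabditis elegans pharyngeal neural network. Provides a
    phenomenological simulator of EPG traces with per-transient ground truth
    (wild-type, serotonin-stimulated and eat-4 mutant phenotype presets, drug
    wash-in and optogenetic illumination schedules), zero-phase Bessel
    high-pass drift removal, threshold-based detection and phase labelling of
    pump events (e, E, P, R, r), computation of the standard per-recording
    EPG summary parameters, condition time-courses, and sorting of worms into
    wild-type and mutant classes using 3-standard-deviation reference bounds
    on pump duration and P-wave count. Includes a command-line interface for
    simulate/analyze/sort workflows on delimited-text trace files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
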