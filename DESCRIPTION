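Package: potcell
Title: Intracellular Passage-of-Time Model of Purkinje Cell Eyeblink Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a cerebellar Purkinje cell that learns the interval between a
    conditional stimulus (CS) and an unconditional stimulus (US) with an intracellular
    passage-of-time mechanism: activation-energy switches gate a "write" process that
    releases drifting, diffusing recorder units whose states encode elapsed time, a
    cumulative archive that stores the interval distribution, and a "read" process that
    converts a sampled fraction of the archive into a precisely timed inhibitory current.
    The membrane is a leaky integrate-and-fire neuron with a Poisson pacemaker, so
    conditioning yields an adaptively timed pause in tonic simple-spike firing. Ships the
    standard delay-conditioning protocols (acquisition, probe batteries, extinction,
    interleaved and compound-stimulus trials, ISI/ITI sweeps) as reproducible experiments,
    plus the measurement layer: peristimulus time histograms, conditioned-response
    detection, pause timing features, and the trials-to-acquisition law.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
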