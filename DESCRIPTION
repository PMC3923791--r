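Package: tstdp
Title: Triplet Spike-Timing-Dependent Plasticity Rules and a Subthreshold
    Synapse Circuit Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating pair- and triplet-based spike-timing-dependent
    plasticity (STDP) with nearest-spike interaction, and a behavioral model of
    a compact subthreshold CMOS synapse circuit that implements the triplet
    rule on an accelerated timescale. Includes generators for the standard
    stimulation protocols (pairing, frequency-dependent pairing, triplets,
    quadruplets, Poissonian rate pairs), event-driven and ramp-based weight
    update simulators, BCM-like rate sweeps, normalized-mean-square-error
    fitting of rule parameters or circuit bias voltages by derivative-free
    simplex search, a synthetic weight-change dataset generator, and
    Monte-Carlo transistor-mismatch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
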