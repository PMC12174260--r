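Package: cmcsim
Title: Stochastic Boolean Simulation of Cerebellar Micro-Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates populations of cerebellar micro-complexes (mossy and
    climbing fibre afferents, granule, Golgi, inhibitory interneuron and
    Purkinje cells projecting to the deep cerebellar nucleus) as stochastic
    Boolean circuits in which every synaptic event contributes a uniformly
    random drive scaled by a synaptic strength and thresholded against a
    depolarisation threshold.  Firing rates are encoded as per-sample firing
    probabilities.  The package closes the loop through a cerebellar-brain-
    inhibition comparator network driving an idealised flexor/extensor joint,
    supports activity-dependent LTP/LTD plasticity with relaxation to
    baseline, a temporal-summation variant with an absolute refractory
    period, pathology presets (micro-complex loss, ethanol, KCNA1 and
    CACNA1A channelopathies, tonic DCN bias), and analysis utilities
    (intention-tremor metric, Morse-wavelet spectrograms, input-output
    frequency sweeps and circuit-count requirement searches), together with
    exact analytic oracles for the firing probabilities of threshold
    crossings of signed sums of scaled uniform draws.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
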