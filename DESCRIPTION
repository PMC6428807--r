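Package: spikevar
Title: Trial-to-Trial Variability and Stimulus Discrimination in Evoked
    Multi-Electrode Array Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for evoked network responses recorded on
    multi-electrode arrays under two pharmacological conditions (intact
    and blocked synaptic inhibition). Extracts 500-ms response windows,
    screens them by peri-stimulus time histogram amplitude, and derives
    four response representations (population rate, per-electrode binary
    words, first-spike latencies and recruitment orders). Quantifies
    trial-to-trial dispersion with cosine-distance single-linkage
    dendrograms and the C 1/3 cluster-content statistic, stimulus
    separability with a normalized contrast index and support-vector
    classification (including cross-condition transfer), and spatial
    propagation with conditional firing probability delay profiles and
    latency maps. Includes a synthetic traveling-wave spike generator
    that emulates both conditions, spike-time jitter and subsampling
    surrogate controls, and exact paired signed-rank inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
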