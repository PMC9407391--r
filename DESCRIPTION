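Package: dendromorph
Title: Dendritic Arbor Segmentation, Morphometry, and Time-Lapse Dynamics
Version: 0.1.0
Authors@R:
    person("Dendromorph", "Developers", email = "dendromorph@example.org",
           role = c("aut", "cre"))
Description: Quantification stack for single-neuron dendritic arbors imaged by
    fluorescence microscopy. Provides a synthetic arbor simulator with ground
    truth labels, automatic dendrite segmentation (a classical multiscale
    ridge-filter baseline and a small trainable convolutional segmenter)
    producing per-pixel probability maps with gap-filling and fragment-removal
    postprocessing, skeleton morphometrics (total dendrite length, terminal
    tip counts, territory coverage, Sholl profiles), two-time-point dendrite
    dynamics (stable, eliminated, and added branch accounting with survival
    rates), and a statistics layer (ANOVA with Tukey, Kruskal-Wallis with
    Dunn and Benjamini-Hochberg, two-way interaction tests, t tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
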