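Package: capscreen
Title: Simulation and Quantification for Zebrafish Motor-Axon Compound Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated in vivo compound screens that use growth of
    zebrafish caudal primary (CaP) motor axons beyond the horizontal myoseptum
    as a read-out of neuromuscular synapse stabilisation. Provides a
    ground-truth-emitting synthetic embryo image generator that emulates
    lateral-view plate imaging of the trunk, automated axon tracing with
    path-length, myoseptum-crossing, branch and abnormality scoring, synaptic
    puncta quantification (area, count, intensity and pre/post overlap) in a
    fixed region of interest at the myoseptum, and two-stage screen statistics:
    toxicity exclusion, rescue-index hit calling, percent-of-control axon
    length, normality-gated group comparisons with post-hoc tests and observed
    power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    igraph,
    multcomp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
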