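Package: l1resp
Title: Response Analysis for In Vivo Calcium Imaging of Spinal Projection Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse (and simulate) in vivo GCaMP calcium-imaging
    recordings of lamina I spinoparabrachial projection neurons under thermal,
    mechanical and electrical stimulation of the hind paw. Encodes the eight
    Peltier ramp-and-hold stimulus protocols as data, renders them to sampled
    stimulus timelines, extracts background-subtracted dF/F traces from image
    stacks or trace tables, detects per-stimulus responses with a 70 percent
    plus 4 standard deviation baseline criterion, estimates per-cell thermal
    thresholds from simple ramp series, and aggregates calls into
    postmortem-normalised response percentages, polymodality tables and
    correlation-sorted heatmap summaries. A ground-truthed synthetic-population
    generator (thermal tuning, adaptation, baseline priming, indicator
    kinetics, rendered image stacks) makes every stage testable end to end.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
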