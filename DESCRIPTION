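Package: meioscope
Title: Automated Measurement of Synaptonemal Complexes and Crossover
    Patterning in Meiotic Spreads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures single synaptonemal-complex bivalents in three-channel
    immunofluorescence images of pachytene spermatocyte spreads: segments
    candidate chromosomes from the SYCP3 (red) channel, extracts a sub-pixel
    straightened midline to quantify SC length, localizes MLH1 crossover foci
    (green) and the CREST-marked centromere (blue) along the midline, applies
    rule-based curation to remove merged-bivalent and spurious-focus errors,
    and computes crossover-patterning statistics: per-mouse and group count
    summaries, focus-class tables, normalized position distributions, gamma
    interference shape (nu), the intra-chromosomal genetic-shuffling measure
    r-bar, permutation tests of variance, and a logistic model of focus
    number on SC length. A seeded generator of synthetic spreads with exact
    ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
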