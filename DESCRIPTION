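Package: rosettrack
Title: Time-Lapse Rosette Growth Phenotyping from Top-View Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated extraction of rosette growth traits from time-lapse
    top-view images of Arabidopsis plants grown in multi-pot flats under
    seasonally variable chamber light. Implements a size-weighted colour
    filter, a dynamic hierarchical background-threshold model, watershed
    rosette detection with day-to-day area feedback, growth-trait extraction
    (rosette area, radius, circular area, compactness), normalization of
    growth curves onto a relative developmental timescale, and quantitative
    genetic analysis (broad-sense heritability trajectories and multifactorial
    variance partitioning). Ships a synthetic flat-image generator with ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    jsonlite,
    png,
    jpeg,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
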