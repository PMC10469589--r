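Package: poolnorm
Title: Read-Count Based Normalization of Multiplexed Sequencing Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes re-pooling transfer volumes that equalize per-library
    sequencing depth in large multiplexed pools, using read (or on-target
    feature) counts from a shallow index run rather than fluorometric
    quantification. Generates acoustic-dispenser (Echo) cherry-pick picklists,
    quantifies depth evenness (coefficient of variation, rarefaction sample
    retention), converts pool quantification to sequencer loading dilutions,
    and ships a pooling-and-sequencing simulator for validating the workflow
    on a 384-library design without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
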