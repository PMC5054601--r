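Package: dropmda
Title: Droplet-Partitioned Multiple Displacement Amplification: Simulation
    and Coverage-Uniformity Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of multiple displacement amplification
    (MDA) of mock metagenomic communities, performed either in a single bulk
    reaction or partitioned into millions of picoliter emulsion droplets, and
    the downstream coverage-uniformity analysis used to compare the two:
    per-base depth from alignment records, read filtering (unpaired and
    multi-mapping reads), subsampling to equal data and to a fixed mean
    coverage, coverage breadth, coefficient of variation, Lorenz curves and
    Gini coefficients, and species-abundance recovery. The simulator models
    Poisson loading of template molecules into droplets, heavy-tailed
    per-template amplification gains with capacity-limited competition
    (global in bulk, per-droplet in emulsion), chimeric read pairs,
    contamination artifacts and multi-mapping reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
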