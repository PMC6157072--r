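Package: ocsmate
Title: Optimal Contribution Selection and Mate Allocation by Differential
    Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint optimization of parental contributions and mate allocation
    in breeding and conservation programs. Mating plans are encoded as
    real-valued chromosomes and optimized with a differential-evolution engine
    under mating constraints, with objectives spanning genetic gain, group
    coancestry and progeny inbreeding, epsilon-constraint trade-off targets,
    Pareto-frontier exploration of the gain-diversity trade-off, and a
    genome-editing extension. Includes pedigree- and marker-based coancestry
    construction, a synthetic-population generator and a brute-force oracle
    for small instances.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
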