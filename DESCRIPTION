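Package: herclock
Title: Hybrid Stochastic-Deterministic Modelling of the Zebrafish
    Segmentation Clock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the zebrafish somite segmentation clock as a delayed
    her1/7 negative-feedback oscillator in which the binding and dissociation
    of repressor proteins to the two her1 and two her7 gene copies is treated
    as an exact stochastic process (a delayed direct-method Gillespie sampler
    with time-varying propensities) while mRNA and protein dynamics follow
    delay differential equations.  Supports uncoupled cell ensembles and
    Delta-Notch coupling on a periodic hexagonal lattice, inter-cellular
    parameter variability experiments, a Kolmogorov-Smirnov based detector of
    clock desynchronisation, and estimation of the expression delay between
    the two her1 alleles from spatial transcription-site count profiles,
    including non-parametric bootstrap inference on per-embryo delay samples
    and synthetic-data generators for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
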