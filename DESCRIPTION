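Package: gcresponse
Title: Simulation-Based Inference of the Germinal-Center Affinity-Fitness Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-based forward simulation of germinal-center (GC) B cell
    evolution under a birth-death-mutation process with carrying-capacity
    regulation and a sigmoid affinity-fitness response function; additive
    deep-mutational-scan (DMS) sequence-to-affinity maps; a 5-mer
    context-sensitive somatic hypermutation engine; compact bijective
    ladderized vector (CBLV) tree encodings augmented with per-node
    affinities; a 1D convolutional network trained with a curve-difference
    loss to infer the response-function parameters from encoded phylogenies;
    and summary-statistic matching to infer the remaining simulator
    parameters (carrying capacity, initial population, death rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    ggplot2,
    tibble,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
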