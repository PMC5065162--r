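Package: coopte
Title: Screening for Composite Transposable-Element-Derived Enhancer Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screen for candidate enhancers assembled from several
    transposable elements (TEs) inserted side-by-side within conserved
    non-coding elements (CNEs). Parses RepeatMasker annotations and
    phastCons-style conserved-element tracks, extracts TE copies overlapping
    high-LOD conserved elements, chains proximal TE-derived CNEs into
    composite candidate loci, measures percent identity of each sub-element
    against its TE consensus by local affine-gap alignment, and infers the
    integration branch and relative integration order of each sub-element
    from ortholog presence/absence on a rooted species tree under a
    single-gain (Dollo) model. A synthetic-data generator produces genomes,
    repeat annotations, conservation tracks and presence matrices with known
    ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
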