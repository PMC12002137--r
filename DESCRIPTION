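Package: bcrtol
Title: B Cell Receptor Tolerance-Checkpoint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for autoantigen-specific B cell tolerance-checkpoint
    analysis of antibody repertoires. Provides a miniature germline
    immunoglobulin segment reference with validation, a seeded simulator of
    V(D)J recombination with junctional diversity, somatic hypermutation and
    clonal expansion, germline V/D/J annotation with junction extraction and
    mutation calling, reversion of mutated receptors to their unmutated
    common ancestor, single-linkage clonal partitioning, checkpoint frequency
    statistics (two-sided Fisher exact tests, exact binomial intervals, gene
    usage and CDR3 features), simulation and 1:1 Langmuir fitting of
    single-cycle surface plasmon resonance sensorgrams, and competition-based
    epitope binning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
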