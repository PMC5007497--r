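Package: p53re
Title: Discovery and Annotation of p53 Response Elements in Genome Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover candidate p53 response elements (REs) in a
    genome and to nominate target genes. Implements exact scanning for the
    degenerate bipartite motif RRRCWWGYYYN{0,15}RRRCWWGYYY (two decameric
    half-sites separated by a variable 0-15 bp spacer), half-site position
    weight matrix (PWM) construction with log-odds scoring and exact
    p-values by dynamic-programming convolution, gene-context annotation
    (TSS distance, gene-region labels, strand concordance, repeat overlap)
    with summary statistics, a PWM-seeded similarity re-search that ranks
    candidate sites by E-value and p-value and intersects the significant
    sets, deterministic candidate prioritization helpers, and a synthetic
    genome simulator with planted motifs for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
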