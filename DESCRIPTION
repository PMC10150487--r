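Package: readerstab
Title: Spike-In Calibrated mRNA Stability, Alternative Polyadenylation and
    m6A Reader Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transcript-metabolism experiments around
    cytoplasmic m6A reader proteins: ERCC spike-in calibrated estimation of
    per-gene mRNA decay constants and half-lives from actinomycin-D time
    courses, construction of poly(A) clusters (PACs) from 3'-end tag data
    with Fisher-exact testing of alternative-polyadenylation shifts and
    TPM-weighted 3'UTR lengths, classification of genes by CLIP/m6A peak
    membership, ribosome-profiling translation efficiency, and
    target-group stratified comparisons with the Mann-Whitney U test.
    Includes a synthetic-data generator that emulates the post-alignment
    products of these assays with machine-readable ground truth, so the
    whole pipeline is exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
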