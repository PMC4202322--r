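Package: mirglass
Title: Cross-Species Conservation of Developmental microRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Compares microRNA expression across the development of two
    species from small-RNA sequencing data. Implements fractional counting
    of multi-mapping 19-24 nt reads against hairpin references, low-count
    filtering and reads-per-million normalisation, replicate averaging and
    developmental stage pooling, ortholog sequence divergence
    (substitutions per site from global affine alignment), genomic miRNA
    cluster detection, all-versus-all stage correlation matrices with
    hierarchical clustering, per-ortholog temporal profile conservation
    against clustered-miRNA and random-pair controls, and an hourglass
    profile of stage-wise expression conservation. A synthetic two-species
    data generator with controllable stage-dependent divergence makes the
    whole pipeline verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
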