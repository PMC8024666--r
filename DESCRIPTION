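Package: nchotspot
Title: Detection of Recurrently Mutated Noncoding Hotspots in Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pan-cancer discovery of noncoding somatic mutation hotspots.
    Fits a donor-specific, covariate-corrected logistic background mutation
    model (chromatin marks, replication timing, trinucleotide context and
    other genomic features), scans small fixed-width windows (default 11 bp)
    centred on recurrently mutated sites with an exact Poisson-binomial
    recurrence test, applies Bonferroni control, and annotates hits by
    genomic element (promoter within 5 kb of a TSS, UTR, intron, intergenic).
    Includes a megabase-scale covariate/mutation-rate correlation module and
    a synthetic-cohort simulator (genome, covariate tracks, donor mutation
    sets, injectable clustered hotspots) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse
Config/testthat/edition: 3
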