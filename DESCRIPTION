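Package: bsamap
Title: Bulked Segregant Analysis Mapping of Recessive Loci from Pooled
    Sequencing
Version: 0.1.0
Authors@R:
    person("bsamap", "authors", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Localizes a recessive Mendelian locus from bulked segregant
    analysis (BSA-seq) of two phenotypic pools sequenced as DNA mixtures.
    Provides a seeded F2 pooled-sequencing simulator (Mendelian
    segregation, Haldane recombination, binomial read sampling, VCF
    output), pool-level variant filtering (depth, shared homozygous-alt,
    shared heterozygous sites), per-site association statistics
    (Euclidean distance of pool allele frequencies, G-statistic, delta
    allele frequency), a sliding-window genome scan with top-quantile
    candidate-region calling, ranking of candidate sites by distance to
    the recessive "ideal" allele-frequency pattern, and
    frameshift/premature-stop consequence annotation of coding indels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
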