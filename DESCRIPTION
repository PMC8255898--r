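Package: inflectr
Title: Growth Inflection-Point Analysis and lncRNA Expression Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits the three classical sigmoidal growth models (logistic,
    Gompertz, Von Bertalanffy) to longitudinal body-weight records and derives
    the growth inflection point (turning-point day, turning-point weight and
    maximum daily gain) in closed form. Around the growth analysis it provides
    the downstream transcriptome pipeline used in inflection-point versus
    plateau-phase studies: a lncRNA identification cascade over transcript
    length, exon count, read support and coding-potential scores; TPM
    quantification; an empirical-noise (M, D) differential-expression engine
    with fold-change and probability thresholds; cis-neighbor lncRNA-mRNA
    discovery by Pearson correlation within a genomic window; hypergeometric
    gene-set enrichment with Benjamini-Hochberg adjustment; and two-group
    trait and fatty-acid comparisons. Synthetic-data generators emulate the
    full study design (weighed growth cohorts, annotated toy genomes and
    replicated two-condition negative-binomial expression experiments with
    known ground truth) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    minpack.lm,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
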